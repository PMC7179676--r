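VALID_LOCATIONS <- c("post_signal", "c_terminal", "internal", "post_propeptide")
VALID_DEPTHS <- c("Polyneoptera", "Pterygota", "Hexapoda", "undetermined")

#' Validate a cleavage motif
#'
#' Prohormone convertase cleavage sites are mono- to tetrabasic runs of
#' Lys/Arg (e.g. "R", "KR", "RKR", "RRRR"). Anything else is rejected.
#'
#' @param pattern Character scalar over the alphabet \{K, R\}, length 1-4.
#' @return The pattern, invisibly, if valid; otherwise an error.
#' @export
validate_motif <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("cleavage motif must be a non-empty character scalar", call. = FALSE)
  if (nchar(pattern) > 4L)
    stop(sprintf("cleavage motif '%s' longer than 4 residues", pattern),
         call. = FALSE)
  if (grepl("[^KR]", pattern))
    stop(sprintf("cleavage motif '%s' contains characters outside {K,R}",
                 pattern), call. = FALSE)
  invisible(pattern)
}

new_family_rule <- function(x) {
  required <- c("family_id", "location", "n_flank", "c_flank", "amidated",
                "pglu_expected", "retain_post_signal_basics",
                "length_min", "length_max")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("family rule '%s': missing fields %s",
                 if (is.null(x$family_id)) "<unnamed>" else x$family_id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!x$location %in% VALID_LOCATIONS)
    stop(sprintf("family rule '%s': unknown location '%s'",
                 x$family_id, x$location), call. = FALSE)
  x$n_flank <- as.character(x$n_flank)
  x$c_flank <- as.character(x$c_flank)
  for (m in setdiff(x$n_flank, "signal_peptide")) {
    ok <- tryCatch({validate_motif(m); TRUE}, error = function(e) FALSE)
    if (!ok) stop(sprintf("family rule '%s': malformed n_flank motif '%s'",
                          x$family_id, m), call. = FALSE)
  }
  for (m in x$c_flank) {
    ok <- tryCatch({validate_motif(m); TRUE}, error = function(e) FALSE)
    if (!ok) stop(sprintf("family rule '%s': malformed c_flank motif '%s'",
                          x$family_id, m), call. = FALSE)
  }
  if (is.null(x$allow_precursor_end)) x$allow_precursor_end <- FALSE
  if (!length(x$c_flank) && !isTRUE(x$allow_precursor_end))
    stop(sprintf("family rule '%s': empty c_flank without allow_precursor_end",
                 x$family_id), call. = FALSE)
  if (x$length_min > x$length_max || x$length_min < 1)
    stop(sprintf("family rule '%s': invalid length range", x$family_id),
         call. = FALSE)
  if (is.null(x$ancestral_core)) x$ancestral_core <- NA_character_
  if (is.null(x$core_synthetic)) x$core_synthetic <- FALSE
  if (is.null(x$ancestral_depth)) x$ancestral_depth <- "undetermined"
  if (is.null(x$propeptide_len)) x$propeptide_len <- NA_integer_
  if (is.null(x$secondary_site)) x$secondary_site <- NA_integer_
  structure(x, class = "family_rule")
}

#' @export
print.family_rule <- function(x, ...) {
  cat(sprintf("<family_rule> %s  [%s]\n", x$family_id, x$location))
  cat(sprintf("  n_flank: %s   c_flank: %s%s\n",
              paste(x$n_flank, collapse = "/"),
              paste(x$c_flank, collapse = "/"),
              if (isTRUE(x$allow_precursor_end)) " (or precursor end)" else ""))
  cat(sprintf("  amidated: %s  pGlu: %s  length: %d-%d\n",
              x$amidated, x$pglu_expected, x$length_min, x$length_max))
  invisible(x)
}

#' Load a family-rule registry
#'
#' Reads a YAML rule configuration (one mapping per family) and validates it.
#' With the default \code{path = NULL} the registry of 21 single-copy
#' neuropeptide precursor families shipped with the package is returned.
#' A user configuration given via \code{overrides} is merged by
#' \code{family_id} on top of the base registry.
#'
#' @param path Path to a YAML rule file, or NULL for the packaged default.
#' @param overrides Optional path to a YAML file whose entries replace
#'   base entries with the same \code{family_id} (and append new ones).
#' @return A named list of \code{family_rule} objects, class
#'   \code{family_registry}.
#' @export
load_family_rules <- function(path = NULL, overrides = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "family_rules.yaml", package = "peptevo",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, new_family_rule)
  ids <- vapply(rules, `[[`, "", "family_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate family_id in rule config: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  names(rules) <- ids
  if (!is.null(overrides)) {
    extra <- lapply(yaml::read_yaml(overrides), new_family_rule)
    for (r in extra) rules[[r$family_id]] <- r
  }
  structure(rules, class = "family_registry")
}

#' Serialize a family-rule registry to YAML
#'
#' Inverse of \code{\link{load_family_rules}}: \code{load_family_rules}
#' applied to the written file reproduces the registry.
#'
#' @param registry A \code{family_registry}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_family_rules <- function(registry, path) {
  plain <- lapply(unname(registry), function(r) {
    r <- unclass(r)
    r$n_flank <- as.list(r$n_flank)
    r$c_flank <- as.list(r$c_flank)
    r[!vapply(r, function(v) length(v) == 1 && is.na(v), TRUE)]
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Look up one family's rule
#'
#' Exact-match lookup, case-insensitive on \code{family_id}.
#'
#' @param family_id Family identifier, e.g. "CCAP".
#' @param registry A \code{family_registry}; defaults to the packaged rules.
#' @return The matching \code{family_rule}.
#' @export
rule_for <- function(family_id, registry = load_family_rules()) {
  hit <- which(tolower(names(registry)) == tolower(family_id))
  if (length(hit) != 1L)
    stop(sprintf("unknown family_id '%s'; valid ids: %s", family_id,
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  registry[[hit]]
}
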