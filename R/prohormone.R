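LEGAL_RESIDUES <- c(AA20, "X", "?")

#' Construct a precursor record
#'
#' A precursor is the full prepropeptide: signal peptide plus propeptide.
#' Coordinates are 0-based, half-open throughout the package;
#' \code{signal_end} is the index of the first residue after the signal
#' peptide. 'X' marks unknown residues, '?' unresolved positions from
#' incomplete transcripts.
#'
#' @param id Record identifier.
#' @param residues Amino-acid string (20 AA plus 'X' and '?').
#' @param family_id Neuropeptide family, e.g. "CCAP".
#' @param signal_end 0-based index of the first residue after the signal
#'   peptide.
#' @param species,taxon_order Optional metadata (species name, taxon-group
#'   label such as "Blattodea").
#' @param complete Is the transcript complete? Incomplete precursors may
#'   carry 'X'/'?' inside the mature peptide.
#' @return A \code{precursor} object.
#' @export
new_precursor <- function(id, residues, family_id, signal_end,
                          species = NA_character_,
                          taxon_order = NA_character_, complete = TRUE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) stop("empty precursor sequence", call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% LEGAL_RESIDUES)
  if (length(bad))
    stop(sprintf("precursor '%s': illegal character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  signal_end <- as.integer(signal_end)
  if (signal_end < 0L || signal_end >= nchar(residues))
    stop(sprintf("precursor '%s': signal_end %d outside [0, %d)",
                 id, signal_end, nchar(residues)), call. = FALSE)
  structure(list(id = id, residues = residues, family_id = family_id,
                 signal_end = signal_end, species = species,
                 taxon_order = taxon_order, complete = isTRUE(complete)),
            class = "precursor")
}

#' Fallback signal-peptide boundary
#'
#' The package treats the signal-peptide boundary as an input (predicted
#' externally or supplied by the simulator). This crude fallback simply
#' returns a fixed default length, capped to the sequence; it is approximate
#' and intended only for exploratory use.
#'
#' @param residues Precursor sequence.
#' @param default_length Assumed signal-peptide length (default 20).
#' @return 0-based boundary index.
#' @export
approximate_signal_end <- function(residues, default_length = 20L) {
  min(as.integer(default_length), nchar(residues) - 1L)
}

#' Scan a precursor for cleavage sites
#'
#' Finds all non-overlapping matches of a basic-motif set, scanning left to
#' right with longest-match precedence at each locus. Sites starting inside
#' the signal peptide are excluded.
#'
#' @param precursor A \code{precursor}.
#' @param motifs Character vector of cleavage motifs (K/R strings).
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open) and \code{motif}; zero rows when nothing matches.
#' @export
scan_cleavage_sites <- function(precursor, motifs) {
  motifs <- setdiff(unique(as.character(motifs)), "signal_peptide")
  for (m in motifs) validate_motif(m)
  res <- precursor$residues
  n <- nchar(res)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  motifs <- motifs[order(nchar(motifs), decreasing = TRUE)]
  out <- list()
  i <- precursor$signal_end + 1L  # 1-based scan start: first post-signal residue
  while (i <= n) {
    hit <- NA_character_
    for (m in motifs) {
      w <- nchar(m)
      if (i + w - 1L <= n &&
          substr(res, i, i + w - 1L) == m) { hit <- m; break }
    }
    if (!is.na(hit)) {
      out[[length(out) + 1L]] <- list(start = i - 1L,
                                      end = i - 1L + nchar(hit), motif = hit)
      i <- i + nchar(hit)
    } else i <- i + 1L
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), stringsAsFactors = FALSE))
  data.frame(start = vapply(out, `[[`, 0L, "start"),
             end = vapply(out, `[[`, 0L, "end"),
             motif = vapply(out, `[[`, "", "motif"),
             stringsAsFactors = FALSE)
}

MIN_CORE <- 4L

#' Excise the predicted mature peptide from a precursor
#'
#' Applies the family grammar: locates the N- and C-flank cleavage sites
#' according to \code{rule$location}, cuts the segment between them, and (for
#' amidated families) removes the C-terminal amide-donor Gly from the core.
#' The minimum accepted core length is 4 residues; candidate C-flank sites
#' closer than that to the core start are skipped, which is what keeps e.g.
#' basic residues at the start of a mature peptide from truncating it.
#'
#' @param precursor A \code{precursor}.
#' @param rule The matching \code{family_rule}.
#' @return A \code{mature_peptide}: list with \code{family_id}, \code{core},
#'   \code{start}, \code{end} (0-based half-open, excluding flanks and the
#'   amide Gly), \code{amide_gly} (was a donor Gly removed?), sentinel-aware
#'   \code{n_site}/\code{c_site}, placeholder PTM flags (see
#'   \code{\link{annotate_ptms}}), and \code{warnings}.
#' @export
excise_mature_peptide <- function(precursor, rule) {
  if (!identical(tolower(precursor$family_id), tolower(rule$family_id)))
    stop(sprintf("precursor family '%s' does not match rule '%s'",
                 precursor$family_id, rule$family_id), call. = FALSE)
  res <- precursor$residues
  n <- nchar(res)
  sig <- precursor$signal_end
  warnings <- character()

  motif_union <- union(setdiff(rule$n_flank, "signal_peptide"), rule$c_flank)
  sites <- scan_cleavage_sites(precursor, motif_union)
  is_n <- sites$motif %in% rule$n_flank
  is_c <- sites$motif %in% rule$c_flank

  pick_c_after <- function(core_start) {
    # first C-flank site compatible with a >=MIN_CORE core
    cand <- which(is_c & sites$start >= core_start + MIN_CORE)
    if (length(cand)) sites[cand[1], ] else NULL
  }

  n_site <- c_site <- NULL
  core_start <- core_end <- NA_integer_

  if (rule$location == "post_signal") {
    core_start <- sig
    if (!isTRUE(rule$retain_post_signal_basics)) {
      # an N-flank motif sitting exactly at the signal boundary is a cleavage
      # remnant, not part of the peptide (C-flank motifs there can be genuine
      # peptide residues, e.g. an N-terminal Arg)
      lead <- which(is_n & sites$start == sig)
      if (length(lead)) core_start <- sites$end[lead[1]]
    }
    c_site <- pick_c_after(core_start)
    if (is.null(c_site)) {
      stop(sprintf("precursor '%s' (%s): peptide not found; no C-flank {%s} downstream of the signal peptide",
                   precursor$id, rule$family_id,
                   paste(rule$c_flank, collapse = ",")), call. = FALSE)
    }
    core_end <- c_site$start
    n_sentinel <- "signal_peptide"
  } else if (rule$location == "c_terminal") {
    cc <- which(is_c)
    if (length(cc)) {
      c_site <- sites[cc[length(cc)], ]
      core_end <- c_site$start
    } else if (isTRUE(rule$allow_precursor_end)) {
      c_site <- NULL
      core_end <- n
    } else {
      stop(sprintf("precursor '%s' (%s): peptide not found; no C-flank {%s} site",
                   precursor$id, rule$family_id,
                   paste(rule$c_flank, collapse = ",")), call. = FALSE)
    }
    nn <- which(is_n & sites$end <= core_end - MIN_CORE)
    if (!length(nn) && !is.null(c_site) && isTRUE(rule$allow_precursor_end) &&
        c_site$motif %in% rule$n_flank) {
      # the precursor ends directly with the peptide: the last basic site is
      # the N-flank, not a C-terminal cleavage site
      n_site <- c_site; c_site <- NULL
      core_start <- n_site$end; core_end <- n
    } else {
      if (!length(nn))
        stop(sprintf("precursor '%s' (%s): peptide not found; no N-flank {%s} site upstream of the C-terminal segment",
                     precursor$id, rule$family_id,
                     paste(rule$n_flank, collapse = ",")), call. = FALSE)
      n_site <- sites[nn[length(nn)], ]
      core_start <- n_site$end
    }
    n_sentinel <- NA_character_
  } else if (rule$location %in% c("internal", "post_propeptide")) {
    nn <- which(is_n & sites$start >= sig)
    found <- FALSE
    for (k in nn) {
      cand_start <- sites$end[k]
      cand_c <- pick_c_after(cand_start)
      if (!is.null(cand_c)) {
        n_site <- sites[k, ]; c_site <- cand_c
        core_start <- cand_start; core_end <- cand_c$start
        found <- TRUE; break
      }
    }
    if (!found)
      stop(sprintf("precursor '%s' (%s): peptide not found; no N-flank {%s} / C-flank {%s} pair downstream of the signal peptide",
                   precursor$id, rule$family_id,
                   paste(rule$n_flank, collapse = ","),
                   paste(rule$c_flank, collapse = ",")), call. = FALSE)
    n_sentinel <- NA_character_
  }

  core <- substr(res, core_start + 1L, core_end)
  amide_gly <- FALSE
  if (isTRUE(rule$amidated) && nchar(core) >= 1L &&
      substr(core, nchar(core), nchar(core)) == "G") {
    core <- substr(core, 1L, nchar(core) - 1L)
    core_end <- core_end - 1L
    amide_gly <- TRUE
  }
  if (nchar(core) < MIN_CORE)
    stop(sprintf("precursor '%s' (%s): degenerate peptide of %d residues",
                 precursor$id, rule$family_id, nchar(core)), call. = FALSE)
  if (isTRUE(rule$amidated) && !amide_gly)
    warnings <- c(warnings, "amide signal missing")
  if (nchar(core) < rule$length_min || nchar(core) > rule$length_max)
    warnings <- c(warnings,
                  sprintf("core length %d outside expected range %d-%d",
                          nchar(core), rule$length_min, rule$length_max))
  if (precursor$complete && grepl("[X?]", core))
    warnings <- c(warnings,
                  "core contains unresolved residues although the precursor is flagged complete")
  if (!is.na(rule$secondary_site))
    warnings <- c(warnings,
                  sprintf("potential secondary cleavage site at core position %d (annotated, not applied)",
                          rule$secondary_site))
  if (rule$family_id == "CRF-DH" &&
      identical(precursor$taxon_order, "Dermaptera"))
    warnings <- c(warnings, "low confidence: Dermaptera CRF-DH N-terminus cannot be predicted with certainty")

  structure(list(
    family_id = rule$family_id, core = core,
    start = core_start, end = core_end,
    amide_gly = amide_gly, amidated = NA, pglu = NA,
    n_site = if (is.null(n_site)) "signal_peptide" else n_site,
    c_site = if (is.null(c_site)) "precursor_end" else c_site,
    warnings = warnings), class = "mature_peptide")
}

#' Annotate post-translational modification flags
#'
#' C-terminal amidation is called when excision removed an amide-donor Gly
#' immediately before the C-flank motif (standard peptide-Gly-basic
#' processing); pyroglutamate when the core starts with Gln and the family
#' rule expects pGlu conversion.
#'
#' @param peptide A \code{mature_peptide} from
#'   \code{\link{excise_mature_peptide}}.
#' @param precursor The source \code{precursor}.
#' @param rule The \code{family_rule} used for excision.
#' @return The peptide with \code{amidated} and \code{pglu} filled in.
#' @export
annotate_ptms <- function(peptide, precursor, rule) {
  peptide$amidated <- isTRUE(rule$amidated) && isTRUE(peptide$amide_gly)
  peptide$pglu <- isTRUE(rule$pglu_expected) &&
    substr(peptide$core, 1L, 1L) == "Q"
  peptide
}

#' Excise and annotate in one step
#'
#' @inheritParams annotate_ptms
#' @return An annotated \code{mature_peptide}.
#' @export
process_precursor <- function(precursor, rule = rule_for(precursor$family_id)) {
  annotate_ptms(excise_mature_peptide(precursor, rule), precursor, rule)
}

#' @export
print.mature_peptide <- function(x, ...) {
  cat(sprintf("<mature_peptide> %s  [%d,%d)\n", x$family_id, x$start, x$end))
  cat(sprintf("  %s%s%s\n", x$core,
              if (isTRUE(x$amidated)) "-NH2" else "-OH",
              if (isTRUE(x$pglu)) "  (pGlu N-terminus)" else ""))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# ---- precursor FASTA dialect: id|species|order|family|signal_end|complete ----

#' Read precursors from FASTA
#'
#' Headers follow the dialect
#' \code{id|species|order|family|signal_end|complete}; '?' and 'X' in
#' sequences are preserved verbatim.
#'
#' @param path FASTA file.
#' @return List of \code{precursor} objects.
#' @export
read_precursor_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  lapply(seq_along(seqs), function(i) {
    fields <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    if (length(fields) != 6L)
      stop(sprintf("record %d: header '%s' does not follow id|species|order|family|signal_end|complete",
                   i, names(seqs)[i]), call. = FALSE)
    new_precursor(id = fields[1], residues = as.character(seqs[[i]]),
                  family_id = fields[4], signal_end = as.integer(fields[5]),
                  species = fields[2], taxon_order = fields[3],
                  complete = as.logical(fields[6]))
  })
}

#' Write precursors to FASTA
#'
#' @param precursors List of \code{precursor} objects.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_precursor_fasta <- function(precursors, path) {
  seqs <- Biostrings::BStringSet(vapply(precursors, `[[`, "", "residues"))
  names(seqs) <- vapply(precursors, function(p)
    paste(p$id, p$species, p$taxon_order, p$family_id, p$signal_end,
          p$complete, sep = "|"), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Tabulate excised peptides
#'
#' Runs excision and PTM annotation over a list of precursors and returns a
#' TSV-ready table (coordinates 0-based half-open, flags, flank motifs).
#'
#' @param precursors List of \code{precursor} objects.
#' @param registry Family-rule registry.
#' @return data.frame, one row per successfully processed precursor;
#'   failures are recorded with NA coordinates and the error message.
#' @export
peptide_table <- function(precursors, registry = load_family_rules()) {
  rows <- lapply(precursors, function(p) {
    pep <- tryCatch(process_precursor(p, rule_for(p$family_id, registry)),
                    error = function(e) e)
    if (inherits(pep, "error"))
      return(data.frame(id = p$id, species = p$species,
                        taxon_order = p$taxon_order, family_id = p$family_id,
                        core = NA_character_, start = NA_integer_,
                        end = NA_integer_, amidated = NA, pglu = NA,
                        n_motif = NA_character_, c_motif = NA_character_,
                        note = conditionMessage(pep),
                        stringsAsFactors = FALSE))
    data.frame(id = p$id, species = p$species, taxon_order = p$taxon_order,
               family_id = p$family_id, core = pep$core,
               start = pep$start, end = pep$end,
               amidated = pep$amidated, pglu = pep$pglu,
               n_motif = if (is.character(pep$n_site)) pep$n_site else pep$n_site$motif,
               c_motif = if (is.character(pep$c_site)) pep$c_site else pep$c_site$motif,
               note = paste(pep$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
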