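# Average evolutionary divergence (AED): mean Poisson-corrected p-distance,
# d = -ln(1 - p), over all unordered sequence pairs of an alignment, with
# pairwise deletion of ambiguous sites ('-', 'X', '?') and a column-bootstrap
# standard error.

#' Pairwise p-distance under pairwise deletion
#'
#' Sites where either row carries '-', 'X' or '?' are removed for this pair
#' only; \code{p} is the fraction of remaining sites that differ.
#'
#' @param row_a,row_b Residue strings (or character vectors) of equal length.
#' @return List with \code{p} and \code{n_valid}. If no site survives
#'   deletion, \code{p} is NA and \code{n_valid} 0 (the pair is undefined).
#' @export
pairwise_p_distance <- function(row_a, row_b) {
  a <- if (length(row_a) == 1L) strsplit(row_a, "", fixed = TRUE)[[1]] else row_a
  b <- if (length(row_b) == 1L) strsplit(row_b, "", fixed = TRUE)[[1]] else row_b
  if (length(a) != length(b))
    stop(sprintf("rows differ in length (%d vs %d)", length(a), length(b)),
         call. = FALSE)
  valid <- !(a %in% AMBIGUOUS | b %in% AMBIGUOUS)
  n_valid <- sum(valid)
  if (n_valid == 0L) return(list(p = NA_real_, n_valid = 0L))
  list(p = sum(a[valid] != b[valid]) / n_valid, n_valid = n_valid)
}

#' Poisson-corrected distance
#'
#' \code{d = -ln(1 - p)}, the standard multiple-hit correction for amino-acid
#' p-distances under equal rates.
#'
#' @param p Proportion of differing sites, in [0, 1).
#' @return Corrected distance (>= p).
#' @export
poisson_distance <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p >= 1))
    stop("Poisson correction undefined for p outside [0, 1)", call. = FALSE)
  -log(1 - p)
}

# mean corrected distance over all pairs of a character matrix; NA when no
# pair is defined. Saturated pairs (p = 1) and pairs with no shared valid
# site are excluded; their count is returned.
aed_mean <- function(m) {
  n <- nrow(m)
  total <- 0; k <- 0L; dropped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd <- pairwise_p_distance(m[i, ], m[j, ])
      if (pd$n_valid == 0L || pd$p >= 1) { dropped <- dropped + 1L; next }
      total <- total + poisson_distance(pd$p)
      k <- k + 1L
    }
  }
  list(aed = if (k) total / k else NA_real_, n_pairs = k, dropped = dropped)
}

#' Average evolutionary divergence with bootstrap SE
#'
#' AED is the mean of the per-pair Poisson-corrected distances over all
#' unordered sequence pairs. The standard error is the sample standard
#' deviation of replicate AEDs, each computed after resampling alignment
#' columns with replacement (the standard phylogenetic site bootstrap).
#' Pairs that are undefined (no shared unambiguous site) or saturated
#' (p = 1) are excluded from the mean with a warning.
#'
#' @param msa An \code{msa} (or character matrix) with >= 2 rows.
#' @param n_boot Bootstrap replicate count (default 500).
#' @param seed RNG seed; required whenever \code{n_boot > 0}.
#' @return An \code{aed_result}: list with \code{aed}, \code{se},
#'   \code{n_pairs}, \code{n_dropped_pairs}, \code{n_boot}, \code{seed}.
#' @export
average_evolutionary_divergence <- function(msa, n_boot = 500L, seed = NULL) {
  m <- unclass(msa)
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("AED needs an alignment with at least 2 rows", call. = FALSE)
  point <- aed_mean(m)
  if (is.na(point$aed))
    stop("all sequence pairs are undefined under pairwise deletion",
         call. = FALSE)
  if (point$dropped > 0L)
    warning(sprintf("%d undefined/saturated pair(s) excluded from AED",
                    point$dropped), call. = FALSE)
  se <- NA_real_
  n_boot <- as.integer(n_boot)
  if (n_boot > 0L) {
    if (is.null(seed)) stop("seed is required for the bootstrap", call. = FALSE)
    reps <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        aed_mean(m[, cols, drop = FALSE])$aed
      }, 0)
    })
    se <- stats::sd(reps[!is.na(reps)])
  }
  structure(list(aed = point$aed, se = se, n_pairs = point$n_pairs,
                 n_dropped_pairs = point$dropped, n_boot = n_boot,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "aed_result")
}

#' @export
print.aed_result <- function(x, ...) {
  cat(sprintf("AED = %.5f +/- %.5f (SE, %d bootstrap replicates; %d pairs)\n",
              x$aed, x$se, x$n_boot, x$n_pairs))
  invisible(x)
}

#' Family-level AED summary
#'
#' Computes per-group AED, the median across groups (even group count: mean
#' of the central pair), overall AED on the merged precursor alignment, and
#' overall AED on the mature-peptide columns. Per-group failures are recorded
#' and do not abort the remaining groups.
#'
#' @param per_group_msas Named list of per-group \code{msa} matrices.
#' @param merged Merged precursor \code{msa} (optional).
#' @param peptide_columns Mature-core column \code{msa} (optional).
#' @param n_boot,seed Passed to
#'   \code{\link{average_evolutionary_divergence}}.
#' @return An \code{aed_summary}: list with \code{per_group},
#'   \code{median_aed}, \code{overall_aed}, \code{peptide_overall_aed},
#'   \code{failed_groups}.
#' @export
summarize_family <- function(per_group_msas, merged = NULL,
                             peptide_columns = NULL, n_boot = 500L,
                             seed = 1L) {
  stopifnot(length(per_group_msas) >= 1L)
  per_group <- list(); failed <- character()
  for (g in names(per_group_msas)) {
    r <- tryCatch(
      average_evolutionary_divergence(per_group_msas[[g]], n_boot, seed),
      error = function(e) e)
    if (inherits(r, "error")) {
      failed <- c(failed, stats::setNames(conditionMessage(r), g))
    } else per_group[[g]] <- r
  }
  if (!length(per_group))
    stop("AED failed for every group", call. = FALSE)
  aeds <- vapply(per_group, `[[`, 0, "aed")
  overall <- if (!is.null(merged))
    average_evolutionary_divergence(merged, n_boot, seed) else NULL
  pep <- if (!is.null(peptide_columns))
    average_evolutionary_divergence(peptide_columns, n_boot, seed) else NULL
  structure(list(per_group = per_group,
                 median_aed = stats::median(aeds),
                 overall_aed = overall, peptide_overall_aed = pep,
                 failed_groups = failed),
            class = "aed_summary")
}

#' Tabulate an AED summary
#'
#' @param summary An \code{aed_summary}.
#' @param family_id Optional family label for the table.
#' @return data.frame mirroring the per-group bar-chart layout: one row per
#'   group plus \code{median}, \code{overall_precursor} and
#'   \code{overall_peptide} rows.
#' @export
aed_summary_table <- function(summary, family_id = NA_character_) {
  row1 <- do.call(rbind, lapply(names(summary$per_group), function(g) {
    r <- summary$per_group[[g]]
    data.frame(family_id = family_id, group = g, aed = r$aed, se = r$se,
               n_pairs = r$n_pairs, n_boot = r$n_boot,
               stringsAsFactors = FALSE)
  }))
  extra <- data.frame(
    family_id = family_id,
    group = c("median", "overall_precursor", "overall_peptide"),
    aed = c(summary$median_aed,
            if (is.null(summary$overall_aed)) NA_real_ else summary$overall_aed$aed,
            if (is.null(summary$peptide_overall_aed)) NA_real_ else summary$peptide_overall_aed$aed),
    se = c(NA_real_,
           if (is.null(summary$overall_aed)) NA_real_ else summary$overall_aed$se,
           if (is.null(summary$peptide_overall_aed)) NA_real_ else summary$peptide_overall_aed$se),
    n_pairs = NA_integer_, n_boot = NA_integer_, stringsAsFactors = FALSE)
  rbind(row1, extra)
}
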