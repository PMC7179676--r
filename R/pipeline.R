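# Orchestration: per-family reports (excise -> slice -> AED -> consensus ->
# ancestral call) and the cross-family per-order summary.

seqset_precursors <- function(seqset, family_id) {
  if (!all(c("signal_end", "complete") %in% names(seqset$meta)))
    stop("sequence headers must follow id|species|order|family|signal_end|complete",
         call. = FALSE)
  lapply(seq_along(seqset$seqs), function(i) {
    new_precursor(id = seqset$meta$id[i],
                  residues = gsub("-", "", seqset$seqs[[i]], fixed = TRUE),
                  family_id = family_id,
                  signal_end = seqset$meta$signal_end[i],
                  species = seqset$meta$species[i],
                  taxon_order = seqset$meta$taxon_order[i],
                  complete = seqset$meta$complete[i])
  })
}

#' Run the full per-family analysis
#'
#' For one neuropeptide family: excises the mature peptide from every
#' precursor, computes per-group AED, the median AED across groups, the
#' overall AED on the merged precursor alignment and on the mature-peptide
#' columns, a consensus of the peptide columns, and an ancestral-depth call
#' for the modal peptide. Deterministic given \code{seed}. Failing groups
#' are skipped and recorded.
#'
#' @param family_id Family identifier.
#' @param per_group Named list (group -> \code{sequence_set}) of aligned
#'   precursor sequences in the precursor header dialect.
#' @param registry Family-rule registry.
#' @param n_boot Bootstrap replicates for every AED (default 500).
#' @param seed RNG seed (mandatory).
#' @param realign_hook Optional external aligner command for the merge step
#'   (see \code{\link{merge_alignments}}); without it, per-group alignments
#'   are stacked with terminal-gap padding.
#' @param consensus_threshold Plurality threshold for the consensus.
#' @param min_orders Minimum orders for an ancestral call.
#' @param outgroups Named logical vector of outgroup hits for the modal
#'   peptide (e.g. c(Zygentoma = TRUE)).
#' @return A \code{family_report}: list with \code{family_id},
#'   \code{per_order} (data.frame: group, n_precursors, min/max precursor
#'   length, aed, se), \code{median_aed}, \code{overall_precursor_aed},
#'   \code{overall_peptide_aed}, \code{consensus}, \code{ancestral_call},
#'   \code{peptides} (excision table), \code{skipped_groups}.
#' @export
run_family_report <- function(family_id, per_group,
                              registry = load_family_rules(),
                              n_boot = 500L, seed, realign_hook = NULL,
                              consensus_threshold = 0.5, min_orders = 5L,
                              outgroups = logical()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  rule <- rule_for(family_id, registry)
  stopifnot(length(per_group) >= 1L, !is.null(names(per_group)))

  group_msas <- list(); group_rows <- list(); skipped <- character()
  pep_rows <- list()
  for (g in names(per_group)) {
    res <- tryCatch({
      ss <- per_group[[g]]
      precs <- seqset_precursors(ss, rule$family_id)
      peps <- lapply(precs, function(p) process_precursor(p, rule))
      msa <- as_msa(ss)
      list(ss = ss, precs = precs, peps = peps, msa = msa)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, stats::setNames(conditionMessage(res), g))
      next
    }
    group_msas[[g]] <- res$msa
    lens <- nchar(gsub("-", "", res$ss$seqs, fixed = TRUE))
    pep_rows[[g]] <- data.frame(
      group = g,
      id = vapply(res$precs, `[[`, "", "id"),
      core = vapply(res$peps, `[[`, "", "core"),
      start = vapply(res$peps, `[[`, 0L, "start"),
      end = vapply(res$peps, `[[`, 0L, "end"),
      amidated = vapply(res$peps, `[[`, NA, "amidated"),
      pglu = vapply(res$peps, `[[`, NA, "pglu"),
      stringsAsFactors = FALSE)
    group_rows[[g]] <- data.frame(group = g, n_precursors = length(res$precs),
                                  min_len = min(lens), max_len = max(lens),
                                  stringsAsFactors = FALSE)
  }
  if (!length(group_msas))
    stop(sprintf("family %s: every group failed (%s)", family_id,
                 paste(skipped, collapse = "; ")), call. = FALSE)

  peptides <- do.call(rbind, pep_rows)
  merged <- merge_alignments(group_msas, realign_hook = realign_hook)
  merged_rows <- rownames(merged)
  core_map <- peptides[match(vapply(strsplit(merged_rows, "|", fixed = TRUE),
                                    `[[`, "", 1L), peptides$id), ]
  cores <- data.frame(row = seq_len(nrow(merged)),
                      start = core_map$start, end = core_map$end)
  pep_msa <- slice_peptide_columns(merged, cores)

  summ <- summarize_family(group_msas, merged = merged,
                           peptide_columns = pep_msa,
                           n_boot = n_boot, seed = seed)
  per_order <- do.call(rbind, group_rows)
  per_order$aed <- vapply(per_order$group, function(g)
    summ$per_group[[g]]$aed, 0)
  per_order$se <- vapply(per_order$group, function(g)
    summ$per_group[[g]]$se, 0)

  cons <- consensus_sequence(pep_msa, threshold = consensus_threshold)
  modal <- names(sort(table(peptides$core), decreasing = TRUE))[1]
  occurrence <- vapply(split(peptides$core, peptides$group),
                       function(x) modal %in% x, TRUE)
  anc <- assign_ancestral_depth(modal, occurrence, outgroups = outgroups,
                                min_orders = min_orders)

  structure(list(family_id = rule$family_id, per_order = per_order,
                 median_aed = summ$median_aed,
                 overall_precursor_aed = summ$overall_aed,
                 overall_peptide_aed = summ$peptide_overall_aed,
                 consensus = cons, ancestral_call = anc,
                 peptides = peptides, skipped_groups = skipped,
                 n_boot = n_boot, seed = seed),
            class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf("<family_report> %s (%d groups%s)\n", x$family_id,
              nrow(x$per_order),
              if (length(x$skipped_groups))
                sprintf(", %d skipped", length(x$skipped_groups)) else ""))
  cat(sprintf("  median AED %.5f | overall precursor %.5f | peptide %.5f\n",
              x$median_aed, x$overall_precursor_aed$aed,
              x$overall_peptide_aed$aed))
  cat(sprintf("  consensus: %s\n  ancestral: %s (%s)\n",
              x$consensus$sequence, x$ancestral_call$peptide,
              x$ancestral_call$depth))
  invisible(x)
}

#' Per-order summary across families
#'
#' For every order, the median over families of that order's per-group AED.
#' The reported spread is the standard deviation across families
#' (inter-family spread, not a bootstrap SE).
#'
#' @param reports List of \code{family_report} objects.
#' @return data.frame: \code{taxon_order}, \code{median_aed},
#'   \code{spread_sd}, \code{n_families}. Orders absent from all reports are
#'   omitted.
#' @export
run_order_summary <- function(reports) {
  stopifnot(length(reports) >= 1L)
  rows <- do.call(rbind, lapply(reports, function(r)
    data.frame(family_id = r$family_id, taxon_order = r$per_order$group,
               aed = r$per_order$aed, stringsAsFactors = FALSE)))
  out <- do.call(rbind, lapply(split(rows, rows$taxon_order), function(d)
    data.frame(taxon_order = d$taxon_order[1],
               median_aed = stats::median(d$aed),
               spread_sd = if (nrow(d) > 1L) stats::sd(d$aed) else NA_real_,
               n_families = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$taxon_order), , drop = FALSE]
}

#' Write a family report as TSV files
#'
#' Emits \code{<family>_aed.tsv} (per-order AED rows plus median/overall
#' rows), \code{<family>_peptides.tsv} and \code{<family>_calls.tsv}
#' (consensus + ancestral call) with a fixed column order; floating point is
#' printed to 5 decimals, so identical inputs and seed give byte-identical
#' files.
#'
#' @param report A \code{family_report}.
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
write_family_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, paste0(report$family_id, "_", name))
  aed <- rbind(
    data.frame(group = report$per_order$group, aed = report$per_order$aed,
               se = report$per_order$se, stringsAsFactors = FALSE),
    data.frame(group = c("median", "overall_precursor", "overall_peptide"),
               aed = c(report$median_aed, report$overall_precursor_aed$aed,
                       report$overall_peptide_aed$aed),
               se = c(NA, report$overall_precursor_aed$se,
                      report$overall_peptide_aed$se),
               stringsAsFactors = FALSE))
  utils::write.table(format_num(aed), f("aed.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(format_num(report$peptides), f("peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- data.frame(
    field = c("consensus", "consensus_threshold", "ancestral_peptide",
              "ancestral_depth", "orders_present", "min_orders"),
    value = c(report$consensus$sequence,
              sprintf("%.5f", report$consensus$threshold),
              report$ancestral_call$peptide, report$ancestral_call$depth,
              paste(report$ancestral_call$orders_present, collapse = ","),
              report$ancestral_call$min_orders), stringsAsFactors = FALSE)
  utils::write.table(calls, f("calls.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(f("aed.tsv"), f("peptides.tsv"), f("calls.tsv")))
}
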