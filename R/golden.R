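# Golden fixtures: one synthetic precursor per family, assembled around the
# family's ancestral/consensus mature peptide and the flank motifs its rule
# prescribes. Used for worked examples and as an end-to-end check that each
# grammar recovers exactly the peptide it was transcribed from.

FIXTURE_SIGNAL <- "MKTLIVLSVFALLAVQSEAA"  # 20 residues

neutral_segment <- function(n) {
  # spacer free of K/R so it can never harbour a cleavage site
  pool <- strsplit("SPDQGALNTEMHDVSAEFWG", "", fixed = TRUE)[[1]]
  paste(pool[((seq_len(n) - 1L) %% length(pool)) + 1L], collapse = "")
}

#' Build the golden fixture precursor for one family
#'
#' Assembles a synthetic precursor around the family's recorded ancestral (or
#' consensus stand-in) peptide: a 20-residue synthetic signal peptide, neutral
#' spacers, the rule's first N- and C-flank motifs, and an amide-donor Gly
#' where the family is amidated. The trissin fixture keeps the three unknown
#' 'X' positions of the ancestral sequence and is therefore flagged
#' incomplete.
#'
#' @param family_id Family identifier.
#' @param registry Family-rule registry.
#' @return A \code{precursor}.
#' @export
family_fixture <- function(family_id, registry = load_family_rules()) {
  rule <- rule_for(family_id, registry)
  core <- rule$ancestral_core
  if (is.na(core))
    stop(sprintf("family '%s' has no recorded ancestral core", family_id),
         call. = FALSE)
  gly <- if (isTRUE(rule$amidated)) "G" else ""
  cflank <- if (length(rule$c_flank)) rule$c_flank[1] else ""
  nflank1 <- setdiff(rule$n_flank, "signal_peptide")
  nflank <- if (length(nflank1)) nflank1[1] else ""
  tail <- neutral_segment(10L)

  res <- switch(rule$location,
    post_signal = paste0(FIXTURE_SIGNAL, core, gly, cflank, tail),
    c_terminal = if (isTRUE(rule$allow_precursor_end) && cflank == "" ||
                     rule$family_id == "AST-CC")
        paste0(FIXTURE_SIGNAL, neutral_segment(20L), nflank, core, gly)
      else
        paste0(FIXTURE_SIGNAL, neutral_segment(20L), nflank, core, gly,
               cflank, tail),
    internal = paste0(FIXTURE_SIGNAL, neutral_segment(20L), nflank, core,
                      gly, cflank, tail),
    post_propeptide = paste0(
      FIXTURE_SIGNAL,
      neutral_segment(if (is.na(rule$propeptide_len)) 20L else rule$propeptide_len),
      nflank, core, gly, cflank, tail))

  new_precursor(id = paste0("golden_", rule$family_id),
                residues = res, family_id = rule$family_id,
                signal_end = nchar(FIXTURE_SIGNAL),
                species = "synthetic", taxon_order = "synthetic",
                complete = !grepl("[X?]", core))
}

#' Excision results over all golden fixtures
#'
#' Runs excision and PTM annotation on every family's golden fixture.
#'
#' @param registry Family-rule registry.
#' @return data.frame with one row per family: excised core, its length,
#'   whether it matches the recorded ancestral core exactly, and PTM flags.
#' @export
golden_peptide_table <- function(registry = load_family_rules()) {
  rows <- lapply(names(registry), function(fid) {
    rule <- registry[[fid]]
    pep <- process_precursor(family_fixture(fid, registry), rule)
    data.frame(family_id = fid, core = pep$core, length = nchar(pep$core),
               matches_ancestral = identical(pep$core, rule$ancestral_core),
               amidated = pep$amidated, pglu = pep$pglu,
               core_synthetic = isTRUE(rule$core_synthetic),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
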