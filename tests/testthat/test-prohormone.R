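reg <- load_family_rules()

toy <- function(residues, family = "CCAP", signal_end = 0L, ...)
  new_precursor("toy", residues, family, signal_end, ...)

test_that("cleavage-site scanning finds non-overlapping longest matches", {
  expect_equal(scan_cleavage_sites(toy("AAKRAA"), "KR"),
               data.frame(start = 2L, end = 4L, motif = "KR",
                          stringsAsFactors = FALSE))
  # longest-match precedence: RKR wins over the embedded KR
  expect_equal(scan_cleavage_sites(toy("AARKRAA"), c("KR", "RKR")),
               data.frame(start = 2L, end = 5L, motif = "RKR",
                          stringsAsFactors = FALSE))
  expect_equal(nrow(scan_cleavage_sites(toy("AADEAA"), c("KR", "R"))), 0L)
  # sites inside the signal peptide are excluded
  hit <- scan_cleavage_sites(toy("AKRAAAKRAA", signal_end = 4L), "KR")
  expect_equal(hit$start, 6L)
})

test_that("precursor validation catches bad input", {
  expect_error(new_precursor("p", "AC#DE", "CCAP", 1L), "illegal character")
  expect_error(new_precursor("p", "ACDE", "CCAP", 9L), "signal_end")
  expect_error(new_precursor("p", "", "CCAP", 0L), "empty")
  expect_silent(new_precursor("p", "AC?XDE", "CCAP", 1L))
})

test_that("post-propeptide excision recovers CCAP from a toy precursor", {
  sig <- strrep("A", 20)
  pro <- strrep("S", 25)
  p <- toy(paste0(sig, pro, "KR", "PFCNAFTGC", "G", "KKR", "DSTNAE"),
           signal_end = 20L)
  pep <- process_precursor(p, rule_for("CCAP", reg))
  expect_identical(pep$core, "PFCNAFTGC")
  expect_true(pep$amidated)
  expect_identical(substr(p$residues, pep$start + 1, pep$end), pep$core)
  expect_identical(pep$n_site$motif, "KR")
  expect_identical(pep$c_site$motif, "KKR")
})

test_that("internal excision yields the 31-residue CT-DH core", {
  sig <- strrep("A", 20)
  core <- "GLDLGLSRGFSGSQAAKHLMGLAAANYAGGP"
  p <- toy(paste0(sig, "SPDQGALNTE", "KR", core, "G", "RRRR", "DSTNAE"),
           family = "CT-DH", signal_end = 20L)
  pep <- process_precursor(p, rule_for("CT-DH", reg))
  expect_identical(pep$core, core)
  expect_equal(nchar(pep$core), 31L)
  expect_true(pep$amidated)
})

test_that("a C-terminal peptide may run to the precursor end", {
  sig <- strrep("A", 20)
  p <- toy(paste0(sig, "SPDQGALNTE", "RR", "GQQKGRVYWRCYFNAVTCF"),
           family = "AST-CC", signal_end = 20L)
  pep <- process_precursor(p, rule_for("AST-CC", reg))
  expect_identical(pep$core, "GQQKGRVYWRCYFNAVTCF")
  expect_identical(pep$c_site, "precursor_end")
  expect_false(pep$amidated)
})

test_that("PTM annotation follows the Gly-donor and pGlu conventions", {
  sig <- strrep("A", 20)
  cor <- toy(paste0(sig, "QTFQYSRGWTN", "G", "RKR", "DSTNAE"),
             family = "corazonin", signal_end = 20L)
  pep <- process_precursor(cor, rule_for("corazonin", reg))
  expect_true(pep$amidated)
  expect_true(pep$pglu)

  # proctolin: monobasic C-flank, no Gly, no amide, no pGlu expectation
  pro <- toy(paste0(sig, "RYLPT", "R", "DSTNAE"),
             family = "proctolin", signal_end = 20L)
  pep2 <- process_precursor(pro, rule_for("proctolin", reg))
  expect_identical(pep2$core, "RYLPT")
  expect_false(pep2$amidated)
  expect_false(pep2$pglu)

  # amidated family without the donor Gly: flagged, not an error
  cor2 <- toy(paste0(sig, "QTFQYSRGWTN", "RKR", "DSTNAE"),
              family = "corazonin", signal_end = 20L)
  pep3 <- process_precursor(cor2, rule_for("corazonin", reg))
  expect_false(pep3$amidated)
  expect_true("amide signal missing" %in% pep3$warnings)
})

test_that("missing flanks and degenerate segments raise diagnostic errors", {
  sig <- strrep("A", 20)
  p <- toy(paste0(sig, "PFCNAFTGC", "G", "DSTNAE"), signal_end = 20L)
  expect_error(process_precursor(p, rule_for("CCAP", reg)),
               "peptide not found")
  # C-flank closer than the 4-residue minimum: skipped, diagnostic error
  q <- toy(paste0(sig, "QTF", "RKR"), family = "corazonin", signal_end = 20L)
  expect_error(process_precursor(q, rule_for("corazonin", reg)),
               "peptide not found")
})

test_that("excision is deterministic and preserves unresolved-residue policy", {
  fix <- family_fixture("trissin", reg)
  expect_false(fix$complete)
  a <- process_precursor(fix, rule_for("trissin", reg))
  b <- process_precursor(fix, rule_for("trissin", reg))
  expect_identical(a, b)
  expect_false(any(grepl("complete", a$warnings)))

  # an 'X' inside the core of a supposedly complete precursor is flagged
  sloppy <- new_precursor(fix$id, fix$residues, fix$family_id, fix$signal_end,
                          complete = TRUE)
  pep <- process_precursor(sloppy, rule_for("trissin", reg))
  expect_true(any(grepl("unresolved", pep$warnings)))
})

test_that("precursor FASTA dialect round-trips", {
  reg_local <- load_family_rules()
  precs <- lapply(c("CCAP", "proctolin", "trissin"), family_fixture, reg_local)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_precursor_fasta(precs, tmp)
  back <- read_precursor_fasta(tmp)
  expect_length(back, 3L)
  for (i in seq_along(precs)) {
    expect_identical(back[[i]]$residues, precs[[i]]$residues)
    expect_identical(back[[i]]$signal_end, precs[[i]]$signal_end)
    expect_identical(back[[i]]$complete, precs[[i]]$complete)
  }
  tab <- peptide_table(back, reg_local)
  expect_equal(nrow(tab), 3L)
  expect_false(any(is.na(tab$core)))
})

test_that("the sNPF secondary cleavage site is annotated, never applied", {
  pep <- process_precursor(family_fixture("sNPF", reg), rule_for("sNPF", reg))
  expect_identical(pep$core, "SNRSPSLRLRF")
  expect_true(any(grepl("secondary cleavage", pep$warnings)))
})
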