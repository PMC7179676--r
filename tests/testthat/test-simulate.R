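reg <- load_family_rules()

test_that("sequence evolution honours branch length zero and determinism", {
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  expect_identical(paste(evolve_sequence(s, 0), collapse = ""), s)
  a <- withr::with_seed(5, evolve_sequence(s, 0.4))
  b <- withr::with_seed(5, evolve_sequence(s, 0.4))
  expect_identical(a, b)
  # protected positions never change
  prot <- withr::with_seed(6, evolve_sequence(s, 5, protected = 1:10))
  expect_identical(paste(prot[1:10], collapse = ""), substr(s, 1, 10))
  # unknown characters cannot evolve
  q <- withr::with_seed(7, evolve_sequence("??XX", 10))
  expect_identical(q, c("?", "?", "X", "X"))
})

test_that("substitution probability matches the 20-state model expectation", {
  n <- 10000L
  s <- paste(rep("A", n), collapse = "")
  out <- withr::with_seed(83, evolve_sequence(s, 0.5))
  p_obs <- mean(out != "A")
  p_exp <- expected_p_distance(0.5)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("simulated family sets are reproducible and truth-consistent", {
  cfg <- sim_config(rule_for("CT-DH", reg), seed = 77)
  s1 <- simulate_family_set(cfg)
  s2 <- simulate_family_set(cfg)
  expect_identical(s1$sequences$seqs, s2$sequences$seqs)

  tr <- s1$truth
  expect_identical(dim(tr$expected_subs), c(55L, 55L))
  expect_true(isSymmetric(tr$expected_subs))
  # star-tree path lengths satisfy the triangle inequality
  d <- tr$expected_subs
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  # planted coordinates point at the emitted cores
  for (i in seq_len(nrow(tr$coords)))
    expect_identical(substr(s1$sequences$seqs[[i]], tr$coords$start[i] + 1L,
                            tr$coords$end[i]), tr$coords$core[i])
})

test_that("zero depth reproduces the ancestor and zero AED", {
  cfg <- sim_config(rule_for("CCAP", reg), n_groups = 3L, taxa_per_group = 3L,
                    group_depths = c(g1 = 0, g2 = 0, g3 = 0),
                    taxon_depth = 0, seed = 12)
  sim <- simulate_family_set(cfg)
  expect_length(unique(unname(sim$sequences$seqs)), 1L)
  r <- average_evolutionary_divergence(as_msa(sim$sequences), n_boot = 0)
  expect_equal(r$aed, 0)
})

test_that("excision recovers planted coordinates on default-config output", {
  rule <- rule_for("MS", reg)
  sim <- simulate_family_set(sim_config(rule, seed = 31))
  precs <- seqset_list <- lapply(seq_along(sim$sequences$seqs), function(i) {
    m <- sim$sequences$meta
    new_precursor(m$id[i], sim$sequences$seqs[[i]], m$family_id[i],
                  m$signal_end[i], m$species[i], m$taxon_order[i],
                  m$complete[i])
  })
  for (i in seq_along(precs)) {
    pep <- process_precursor(precs[[i]], rule)
    expect_identical(pep$start, sim$truth$coords$start[i])
    expect_identical(pep$end, sim$truth$coords$end[i])
  }
})

test_that("core conservation emerges from the rate multipliers", {
  sim <- simulate_family_set(sim_config(rule_for("SIFamide", reg), seed = 19))
  m <- as_msa(sim$sequences)
  regions <- sim$truth$regions
  core <- regions[regions$name == "core", ]
  core_cols <- (core$start + 1):core$end
  core_msa <- structure(unclass(m)[, core_cols],
                        class = c("msa", "matrix", "array"))
  full <- average_evolutionary_divergence(m, n_boot = 0)
  cc <- average_evolutionary_divergence(core_msa, n_boot = 0)
  expect_lt(cc$aed, full$aed)
})

test_that("linker indels shift coordinates but excision still recovers them", {
  rule <- rule_for("CCAP", reg)
  cfg <- sim_config(rule, n_groups = 4L, taxa_per_group = 3L,
                    indel_rate_linker = 0.1, seed = 55)
  sim <- simulate_family_set(cfg)
  lens <- nchar(unname(sim$sequences$seqs))
  expect_gt(length(unique(lens)), 1L)  # indels actually happened
  m <- sim$sequences$meta
  for (i in seq_along(sim$sequences$seqs)) {
    p <- new_precursor(m$id[i], sim$sequences$seqs[[i]], m$family_id[i],
                       m$signal_end[i], complete = m$complete[i])
    pep <- process_precursor(p, rule)
    expect_identical(pep$start, sim$truth$coords$start[i])
    expect_identical(pep$end, sim$truth$coords$end[i])
  }
})

test_that("masking emulates incomplete transcripts", {
  cfg <- sim_config(rule_for("NPF-1", reg), n_groups = 3L, taxa_per_group = 2L,
                    mask_rate = 0.2, seed = 91)
  sim <- simulate_family_set(cfg)
  expect_true(any(grepl("?", sim$sequences$seqs, fixed = TRUE)))
  expect_true(any(!sim$sequences$meta$complete))
})

test_that("configuration validation rejects bad settings", {
  rule <- rule_for("CCAP", reg)
  expect_error(sim_config(rule), "seed is mandatory")
  expect_error(sim_config(rule, rate_multipliers = list(core = 2, linker = 1,
                                                        signal = 1), seed = 1),
               "core")
  expect_warning(sim_config(rule, ancestral_core = "PFCN", seed = 1),
                 "outside the rule's expected range")
})
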