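test_that("p-distance applies pairwise deletion of ambiguous sites", {
  expect_equal(pairwise_p_distance("RYLPT", "RYLPT"), list(p = 0, n_valid = 5L))
  expect_equal(pairwise_p_distance("RYLPT", "RYLPV"),
               list(p = 0.2, n_valid = 5L))
  expect_equal(pairwise_p_distance("RY?PT", "RYLPV"),
               list(p = 0.25, n_valid = 4L))
  # '-' and 'X' are treated exactly like '?'
  expect_equal(pairwise_p_distance("RY-PT", "RYLPV")$n_valid, 4L)
  expect_equal(pairwise_p_distance("RYXPT", "RYLPV")$n_valid, 4L)
  expect_equal(pairwise_p_distance("???", "ACD"), list(p = NA_real_, n_valid = 0L))
  expect_error(pairwise_p_distance("ACDE", "ACD"), "differ in length")
})

test_that("Poisson correction matches the closed form and rejects saturation", {
  expect_equal(poisson_distance(0), 0)
  expect_equal(poisson_distance(0.2), -log(0.8), tolerance = 1e-12)
  expect_gte(poisson_distance(0.5), 0.5)
  expect_error(poisson_distance(1), "undefined")
  expect_error(poisson_distance(-0.1), "undefined")
})

test_that("AED matches hand-computed pair means and is seed-deterministic", {
  m <- as_msa(c(a = "RYLPT", b = "RYLPV", c = "RYLAT"))
  r <- average_evolutionary_divergence(m, n_boot = 0)
  expect_equal(r$aed, (-log(0.8) - log(0.8) - log(0.6)) / 3, tolerance = 1e-12)
  expect_equal(r$n_pairs, 3L)

  ident <- as_msa(c(a = "RYLPT", b = "RYLPT", c = "RYLPT"))
  ri <- average_evolutionary_divergence(ident, n_boot = 50, seed = 1)
  expect_equal(ri$aed, 0)
  expect_equal(ri$se, 0)

  r1 <- average_evolutionary_divergence(m, n_boot = 100, seed = 9)
  r2 <- average_evolutionary_divergence(m, n_boot = 100, seed = 9)
  expect_identical(r1$se, r2$se)
  expect_error(average_evolutionary_divergence(m, n_boot = 10), "seed")
})

test_that("AED equals the brute-force oracle on random alignments", {
  withr::with_seed(404, {
    for (k in 1:25) {
      m <- random_msa(sample(2:8, 1), sample(5:30, 1))
      expected <- brute_force_aed(m)
      if (is.na(expected)) next
      got <- suppressWarnings(
        average_evolutionary_divergence(m, n_boot = 0)$aed)
      expect_equal(got, expected, tolerance = 1e-12)
    }
  })
})

test_that("AED is invariant under row permutation and all-gap columns", {
  withr::with_seed(7, m <- random_msa(6, 20, gap_prob = 0.05))
  base <- suppressWarnings(average_evolutionary_divergence(m, n_boot = 0)$aed)
  perm <- m[sample(nrow(m)), ]
  expect_equal(
    suppressWarnings(average_evolutionary_divergence(perm, n_boot = 0)$aed),
    base, tolerance = 1e-12)
  padded <- cbind(m, matrix("-", nrow(m), 3))
  expect_equal(
    suppressWarnings(average_evolutionary_divergence(padded, n_boot = 0)$aed),
    base, tolerance = 1e-12)
})

test_that("undefined and saturated pairs are excluded with a warning", {
  m <- rbind(s1 = c("A", "C", "D"), s2 = c("C", "A", "E"),
             s3 = c("A", "C", "D"))
  # s1-s2 and s2-s3 are fully different (p = 1): dropped
  expect_warning(r <- average_evolutionary_divergence(m, n_boot = 0),
                 "excluded")
  expect_equal(r$n_pairs, 1L)
  expect_equal(r$aed, 0)

  allgap <- rbind(a = c("?", "?"), b = c("A", "C"))
  expect_error(suppressWarnings(
    average_evolutionary_divergence(allgap, n_boot = 0)), "undefined")
})

test_that("bootstrap SE shrinks as columns accumulate", {
  ses <- vapply(c(30L, 200L, 2000L), function(nc) {
    withr::with_seed(nc, {
      a <- sample(AA20_test <- c("A", "C", "D", "E"), nc, replace = TRUE)
      b <- ifelse(runif(nc) < 0.3,
                  vapply(a, function(x) setdiff(c("F", "G"), x)[1], ""), a)
      m <- rbind(a = a, b = b)
      average_evolutionary_divergence(m, n_boot = 200, seed = 5)$se
    })
  }, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("family summaries compute medians and tolerate failing groups", {
  g1 <- as_msa(c(a = "RYLPT", b = "RYLPV"))
  g2 <- as_msa(c(a = "RYLPT", b = "RYLAT"))
  g3 <- as_msa(c(a = "RYLPT", b = "RYLPT"))
  s <- summarize_family(list(x = g1, y = g2, z = g3), n_boot = 0)
  aeds <- sort(vapply(s$per_group, `[[`, 0, "aed"))
  expect_equal(s$median_aed, unname(aeds[2]))
  expect_gte(s$median_aed, min(aeds))
  expect_lte(s$median_aed, max(aeds))

  # even group count: mean of the central pair
  s4 <- summarize_family(list(x = g1, y = g2, z = g3, w = g3), n_boot = 0)
  a4 <- sort(vapply(s4$per_group, `[[`, 0, "aed"))
  expect_equal(s4$median_aed, mean(a4[2:3]))

  bad <- matrix("A", 1, 3)  # single row: AED undefined
  s5 <- summarize_family(list(x = g1, broken = bad), n_boot = 0)
  expect_named(s5$failed_groups, "broken")
  expect_equal(length(s5$per_group), 1L)

  single <- summarize_family(list(only = g1), n_boot = 0)
  expect_equal(single$median_aed, single$per_group$only$aed)
})
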