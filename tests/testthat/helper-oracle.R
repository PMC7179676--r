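# Independent brute-force AED oracle: explicit double loop over pairs and
# sites, no code shared with the package implementation.
brute_force_aed <- function(m) {
  gaps <- c("-", "X", "?")
  n <- nrow(m)
  ds <- c()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      diffs <- 0L; valid <- 0L
      for (s in seq_len(ncol(m))) {
        a <- m[i, s]; b <- m[j, s]
        if (a %in% gaps || b %in% gaps) next
        valid <- valid + 1L
        if (a != b) diffs <- diffs + 1L
      }
      if (valid == 0L) next
      p <- diffs / valid
      if (p >= 1) next
      ds <- c(ds, -log(1 - p))
    }
  }
  if (!length(ds)) NA_real_ else mean(ds)
}

# random alignment with occasional gaps/ambiguity, as a plain matrix
random_msa <- function(n_rows, n_cols, gap_prob = 0.1) {
  alpha <- c("A", "C", "D", "E", "F", "G", "H", "K", "R", "-", "X", "?")
  probs <- c(rep((1 - gap_prob) / 9, 9), rep(gap_prob / 3, 3))
  m <- matrix(sample(alpha, n_rows * n_cols, replace = TRUE, prob = probs),
              n_rows, n_cols)
  rownames(m) <- paste0("s", seq_len(n_rows))
  m
}

# group a simulated family set for run_family_report
sim_groups <- function(sim) split_by_group(sim$sequences)
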