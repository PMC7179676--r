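# Precursor-evolution simulator. Sequences evolve under a 20-state
# equal-rates (Jukes-Cantor-type) substitution model, the matched generator
# for the Poisson-corrected distance: per site, a substitution occurs along a
# branch of length t (expected substitutions/site) with probability
# (19/20) * (1 - exp(-(20/19) * rate * t)), to a uniformly chosen different
# residue. Taxa evolve down a star tree of groups (orders), each group a star
# of taxa. With protect_motifs, planted cleavage motifs and the amide-donor
# Gly are frozen and substitutions never introduce new Lys/Arg outside them,
# so the processing grammar of every emitted precursor is exactly the planted
# one and excision recovers the true coordinates by construction.

NONBASIC <- setdiff(AA20, c("K", "R"))

#' Polyneopteran order labels
#'
#' The 11 taxon groups used as the default simulation preset.
#' @return Character vector of order names.
#' @export
polyneoptera_orders <- function() {
  c("Zoraptera", "Dermaptera", "Plecoptera", "Caelifera", "Ensifera",
    "Grylloblattodea", "Mantophasmatodea", "Embioptera", "Phasmatodea",
    "Mantodea", "Blattodea")
}

default_group_depths <- function() {
  c(Zoraptera = 0.30, Dermaptera = 0.45, Plecoptera = 0.45,
    Caelifera = 0.40, Ensifera = 0.40, Grylloblattodea = 0.10,
    Mantophasmatodea = 0.12, Embioptera = 0.35, Phasmatodea = 0.30,
    Mantodea = 0.25, Blattodea = 0.30)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 11 polyneopteran orders with
#' order-specific divergence depths (relict orders such as Grylloblattodea
#' and Mantophasmatodea shallow, Dermaptera/Plecoptera/Orthoptera deep), a
#' strongly conserved mature core (rate multiplier 0.05) between
#' fast-evolving linkers (1.0), frozen cleavage motifs, and no indels.
#'
#' @param family_rule A \code{family_rule} used as the precursor scaffold.
#' @param ancestral_core Root mature-peptide sequence; defaults to the
#'   family's recorded ancestral core.
#' @param n_groups Number of taxon groups (defaults to all 11 orders).
#' @param taxa_per_group Taxa simulated per group.
#' @param group_depths Named numeric: root-to-group branch lengths in
#'   expected substitutions/site.
#' @param taxon_depth Group-to-taxon branch length: a scalar, a named
#'   per-group vector, or NULL (default) for 0.25 * group_depths, which gives
#'   shallow orders proportionally low within-order divergence.
#' @param rate_multipliers List with \code{core} (<= 1), \code{linker}
#'   (>= 1), \code{signal} region rate multipliers.
#' @param protect_motifs Freeze planted motifs/amide Gly and forbid new K/R
#'   outside them (grammar-preserving evolution).
#' @param indel_rate_linker Per-site, per-branch indel probability in linker
#'   regions (half deletions, half insertions).
#' @param signal_len,linker_len,tail_len Region lengths in residues;
#'   propeptide length comes from the rule (fallback 20).
#' @param mask_rate Per-site probability of masking emitted residues with
#'   '?' (emulates incomplete transcripts); masked taxa are flagged
#'   incomplete.
#' @param seed RNG seed (mandatory).
#' @return A validated \code{sim_config}.
#' @export
sim_config <- function(family_rule, ancestral_core = family_rule$ancestral_core,
                       n_groups = 11L, taxa_per_group = 5L,
                       group_depths = NULL, taxon_depth = NULL,
                       rate_multipliers = list(core = 0.05, linker = 1,
                                               signal = 1),
                       protect_motifs = TRUE, indel_rate_linker = 0,
                       signal_len = 20L, linker_len = 20L, tail_len = 10L,
                       mask_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(family_rule, "family_rule"))
  labels <- polyneoptera_orders()
  if (n_groups <= length(labels)) labels <- labels[seq_len(n_groups)]
  else labels <- c(labels, paste0("group", seq_len(n_groups - length(labels))))
  if (is.null(group_depths)) {
    gd <- default_group_depths()
    group_depths <- stats::setNames(
      gd[((seq_len(n_groups) - 1L) %% length(gd)) + 1L], labels)
  } else {
    if (is.null(names(group_depths)))
      names(group_depths) <- labels[seq_along(group_depths)]
    labels <- names(group_depths)
    n_groups <- length(group_depths)
  }
  if (is.null(taxon_depth)) taxon_depth <- 0.25 * group_depths
  taxon_depth <- if (length(taxon_depth) == 1L)
    stats::setNames(rep(taxon_depth, n_groups), labels)
  else stats::setNames(rep_len(taxon_depth, n_groups), labels)
  stopifnot(all(group_depths >= 0), all(taxon_depth >= 0),
            rate_multipliers$core <= rate_multipliers$linker,
            all(unlist(rate_multipliers) >= 0))
  if (is.na(ancestral_core))
    stop("family rule has no ancestral core; supply ancestral_core",
         call. = FALSE)
  if (nchar(ancestral_core) < family_rule$length_min ||
      nchar(ancestral_core) > family_rule$length_max)
    warning(sprintf("ancestral core length %d outside the rule's expected range %d-%d",
                    nchar(ancestral_core), family_rule$length_min,
                    family_rule$length_max), call. = FALSE)
  structure(list(family_rule = family_rule, ancestral_core = ancestral_core,
                 n_groups = n_groups, taxa_per_group = as.integer(taxa_per_group),
                 group_labels = labels, group_depths = group_depths,
                 taxon_depth = taxon_depth, rate_multipliers = rate_multipliers,
                 protect_motifs = isTRUE(protect_motifs),
                 indel_rate_linker = indel_rate_linker,
                 signal_len = as.integer(signal_len),
                 linker_len = as.integer(linker_len),
                 tail_len = as.integer(tail_len),
                 mask_rate = mask_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Evolve a sequence along one branch
#'
#' 20-state equal-rates substitution: per unprotected site i the residue is
#' replaced with probability (19/20) * (1 - exp(-(20/19) * rate_i * t)) by a
#' uniformly chosen different residue. The caller controls the RNG state
#' (seed before calling for reproducibility).
#'
#' @param seq Residue string or character vector.
#' @param branch_length t, expected substitutions/site at rate 1.
#' @param region_rates Per-site rate multipliers (scalar recycled).
#' @param protected Integer positions that never change.
#' @param forbid_targets Residues never used as substitution targets
#'   (e.g. c("K","R") for grammar-preserving evolution).
#' @return Character vector of evolved residues.
#' @export
evolve_sequence <- function(seq, branch_length, region_rates = 1,
                            protected = integer(),
                            forbid_targets = character()) {
  stopifnot(branch_length >= 0)
  chars <- if (length(seq) == 1L) strsplit(seq, "", fixed = TRUE)[[1]] else seq
  n <- length(chars)
  rates <- rep_len(region_rates, n)
  p_sub <- (19 / 20) * (1 - exp(-(20 / 19) * rates * branch_length))
  p_sub[protected] <- 0
  p_sub[!chars %in% AA20] <- 0  # 'X'/'?' cannot evolve
  hit <- which(stats::runif(n) < p_sub)
  for (i in hit) {
    targets <- setdiff(AA20, c(chars[i], forbid_targets))
    chars[i] <- sample(targets, 1L)
  }
  chars
}

# region scaffold for one family: list of (name, class, chars);
# class in {signal, linker, motif, core, amide}
build_regions <- function(config) {
  rule <- config$family_rule
  rand_seg <- function(n) sample(NONBASIC, n, replace = TRUE)
  core <- strsplit(config$ancestral_core, "", fixed = TRUE)[[1]]
  gly <- if (isTRUE(rule$amidated)) list(list(name = "amide", class = "amide",
                                              chars = "G")) else list()
  nfl <- setdiff(rule$n_flank, "signal_peptide")
  nflank <- if (length(nfl)) list(list(name = "n_flank", class = "motif",
    chars = strsplit(nfl[1], "", fixed = TRUE)[[1]])) else list()
  cflank <- if (length(rule$c_flank)) list(list(name = "c_flank",
    class = "motif",
    chars = strsplit(rule$c_flank[1], "", fixed = TRUE)[[1]])) else list()
  sig <- list(list(name = "signal", class = "signal",
                   chars = rand_seg(config$signal_len)))
  corereg <- list(list(name = "core", class = "core", chars = core))
  tail <- list(list(name = "tail", class = "linker",
                    chars = rand_seg(config$tail_len)))
  linker <- function(name, n) list(list(name = name, class = "linker",
                                        chars = rand_seg(n)))
  pro_len <- if (is.na(rule$propeptide_len)) 20L else rule$propeptide_len
  switch(rule$location,
    post_signal = c(sig, corereg, gly, cflank, tail),
    c_terminal = c(sig, linker("linker", config$linker_len), nflank,
                   corereg, gly, cflank, tail),
    internal = c(sig, linker("linker1", config$linker_len), nflank, corereg,
                 gly, cflank, linker("linker2", config$linker_len)),
    post_propeptide = c(sig, linker("propeptide", pro_len), nflank, corereg,
                        gly, cflank, tail))
}

region_rate <- function(class, mult) {
  switch(class, signal = mult$signal, linker = mult$linker,
         core = mult$core, motif = mult$linker, amide = mult$core)
}

evolve_regions <- function(regions, t, config) {
  mult <- config$rate_multipliers
  forbid <- if (config$protect_motifs) c("K", "R") else character()
  lapply(regions, function(reg) {
    frozen <- config$protect_motifs && reg$class %in% c("motif", "amide")
    if (!frozen) {
      reg$chars <- evolve_sequence(reg$chars, t,
                                   region_rate(reg$class, mult),
                                   forbid_targets = forbid)
      if (reg$class == "linker" && config$indel_rate_linker > 0) {
        n <- length(reg$chars)
        keep <- stats::runif(n) >= config$indel_rate_linker / 2
        ins <- stats::runif(n) < config$indel_rate_linker / 2
        out <- character()
        for (i in seq_len(n)) {
          if (keep[i]) out <- c(out, reg$chars[i])
          if (ins[i]) out <- c(out, sample(NONBASIC, 1L))
        }
        reg$chars <- out
      }
    }
    reg
  })
}

#' Simulate a precursor family with ground truth
#'
#' Assembles the ancestral precursor from the family rule (signal peptide,
#' optional propeptide/linkers, flank motifs, mature core, amide-donor Gly),
#' evolves it down a star tree of groups and taxa, and emits the sequences
#' with the planted mature-peptide coordinates and the expected pairwise
#' path lengths.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{sequences} (a \code{sequence_set} in the
#'   precursor header dialect, aligned when no indels occurred),
#'   \code{truth}: \code{coords} (per-taxon 0-based half-open core
#'   coordinates and planted core), \code{regions} (ancestral region layout:
#'   name, class, 0-based start/end), \code{expected_subs} (pairwise tree
#'   path lengths, substitutions/site at rate 1), and the \code{config}.
#' @export
simulate_family_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    root <- build_regions(config)
    headers <- character(); seqs <- character()
    ids <- character(); groups <- character()
    starts <- integer(); ends <- integer(); cores <- character()
    completes <- logical()
    for (g in seq_len(config$n_groups)) {
      glab <- config$group_labels[g]
      ganc <- evolve_regions(root, config$group_depths[[glab]], config)
      td <- config$taxon_depth[[glab]]
      for (k in seq_len(config$taxa_per_group)) {
        taxon <- if (td > 0) evolve_regions(ganc, td, config) else ganc
        lens <- vapply(taxon, function(r) length(r$chars), 0L)
        offs <- cumsum(c(0L, lens))
        nm <- vapply(taxon, `[[`, "", "name")
        core_i <- which(nm == "core")
        residues <- unlist(lapply(taxon, `[[`, "chars"))
        complete <- TRUE
        if (config$mask_rate > 0) {
          mask <- stats::runif(length(residues)) < config$mask_rate
          if (any(mask)) { residues[mask] <- "?"; complete <- FALSE }
        }
        id <- sprintf("%s_%s_t%02d", config$family_rule$family_id, glab, k)
        ids <- c(ids, id); groups <- c(groups, glab)
        starts <- c(starts, offs[core_i]); ends <- c(ends, offs[core_i + 1L])
        cores <- c(cores, paste(taxon[[core_i]]$chars, collapse = ""))
        completes <- c(completes, complete)
        seqs <- c(seqs, paste(residues, collapse = ""))
        headers <- c(headers, paste(id, paste0(glab, "_sp", k), glab,
                                    config$family_rule$family_id,
                                    offs[which(nm == "signal") + 1L],
                                    complete, sep = "|"))
      }
    }
    lens0 <- vapply(root, function(r) length(r$chars), 0L)
    offs0 <- cumsum(c(0L, lens0))
    regions <- data.frame(name = vapply(root, `[[`, "", "name"),
                          class = vapply(root, `[[`, "", "class"),
                          start = offs0[-length(offs0)], end = offs0[-1L],
                          stringsAsFactors = FALSE)
    n_tax <- length(ids)
    gd <- config$group_depths[groups]
    td <- config$taxon_depth[groups]
    exp_subs <- matrix(0, n_tax, n_tax, dimnames = list(ids, ids))
    for (i in seq_len(n_tax)) for (j in seq_len(n_tax)) {
      if (i == j) next
      exp_subs[i, j] <- if (groups[i] == groups[j]) td[[i]] + td[[j]]
        else gd[[i]] + td[[i]] + gd[[j]] + td[[j]]
    }
    truth <- list(coords = data.frame(id = ids, group = groups,
                                      start = starts, end = ends,
                                      core = cores, complete = completes,
                                      stringsAsFactors = FALSE),
                  regions = regions, expected_subs = exp_subs,
                  group_depths = config$group_depths)
    list(sequences = new_sequence_set(seqs, headers),
         truth = truth, config = config)
  })
}

#' Analytic expected p-distance of the substitution model
#'
#' For two sequences separated by total path length t at rate multiplier r,
#' the expected proportion of differing sites is
#' (19/20) * (1 - exp(-(20/19) * r * t)).
#'
#' @param path_length Total tree path length between the two taxa.
#' @param rate Region rate multiplier.
#' @return Expected p.
#' @export
expected_p_distance <- function(path_length, rate = 1) {
  (19 / 20) * (1 - exp(-(20 / 19) * rate * path_length))
}
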