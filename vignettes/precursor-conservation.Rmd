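---
title: "Processing grammars and conservation statistics for single-copy neuropeptide precursors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing grammars and conservation statistics for single-copy neuropeptide precursors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptevo)
```

## The problem

Insect neuropeptides are cut out of larger precursor proteins
(prepropeptides) by prohormone convertases at mono- to tetrabasic Lys/Arg
motifs, trimmed by carboxypeptidases, and often finished by C-terminal
amidation (a Gly immediately preceding the basic site donates the amide) and
N-terminal pyroglutamate formation from Gln. For *single-copy* precursors —
those encoding exactly one bioactive peptide — the mature peptide is under
strong stabilizing selection while the rest of the precursor (signal peptide,
propeptide, linkers) drifts much faster. Comparing divergence of the whole
precursor with divergence of the mature peptide, across the deep lineages of
Polyneoptera (cockroaches, locusts, stick insects and allies), quantifies
that contrast and lets one postulate which peptide sequences were already
present in the ancestors of Polyneoptera, Pterygota, or Hexapoda.

This package implements that analysis as reusable parts:

1. a machine-readable registry of the processing grammars of 21 single-copy
   families (`load_family_rules()`),
2. rule-based excision of mature peptides with PTM annotation
   (`excise_mature_peptide()`, `annotate_ptms()`),
3. alignment I/O with gap-aware peptide-column slicing,
4. the average evolutionary divergence (AED) statistic with a column
   bootstrap (`average_evolutionary_divergence()`),
5. sequence-logo, consensus, and ancestral-depth statistics,
6. a precursor-evolution simulator with full ground truth
   (`simulate_family_set()`), and
7. per-family / per-order report drivers (`run_family_report()`,
   `run_order_summary()`).

## The family grammar

Each family rule records where the peptide sits in the precursor
(`post_signal`, `c_terminal`, `internal`, or `post_propeptide`), the sets of
admissible N- and C-flank cleavage motifs (sets, because several families use
order-specific alternates, e.g. KKR *or* RKR for CCAP's C-flank), whether the
peptide is amidated, whether N-terminal pGlu is expected, and an advisory
mature-length range. Four families are not amidated (AST-CC, elevenin,
proctolin, trissin); the other 17 are. Grammar quirks that matter:

* **CCHamide-2** keeps a KR at its N-terminus: a basic motif directly after
  the signal peptide is not processed, so the rule sets
  `retain_post_signal_basics`.
* **AST-CC and RFLamide** may end directly with the peptide
  (`allow_precursor_end`); when the last basic site of such a precursor is an
  N-flank motif, it is interpreted as the N-flank and the peptide runs to the
  precursor end.
* **Monobasic sites** are honoured only where a family lists them
  (proctolin, AT, HanSolin, AST-CCC, RFLamide); scanning every R/K would
  over-fragment precursors.
* **sNPF** carries a potential secondary cleavage site at core position 3;
  it is reported as an annotation and never applied.

```{r rules}
reg <- load_family_rules()
rule_for("CCAP", reg)
```

Two idiosyncrasies in the source literature were resolved once: published
discussions of allatotropin and CNMamide divergence values appear under the
wrong family names (apparent copy-paste slips), and the registry follows the
family actually being described; and proctolin is printed both as RYLPT and
RYPLT in places — the registry records RYLPT, the form used in
ancestral-sequence statements.

## Excision numerics

Scanning is left-to-right with longest-match precedence over the union of the
family's motif sets, non-overlapping, and skips the signal peptide. Excision
then resolves flanks by location:

* `post_signal`: core from the signal boundary to the *first* downstream
  C-flank site;
* `c_terminal`: the *last* C-flank site (or the precursor end where allowed)
  terminates the core, and the *last* N-flank site compatible with a minimum
  core bounds it on the left;
* `internal` / `post_propeptide`: the first N-flank site downstream of the
  signal peptide that is followed by a compatible C-flank site.

The minimum accepted core is 4 residues; candidate C-flank sites closer than
that to the core start are skipped. This bound is what lets proctolin's own
N-terminal Arg — which matches the family's monobasic C-flank motif — survive
scanning. Shorter segments raise a degenerate-peptide error. For amidated
families a terminal Gly is removed from the core and recorded as the amide
donor; a missing donor Gly in an amidated family is a warning
(`"amide signal missing"`), not an error, since real data contain such
precursors. pGlu is flagged when the core starts with Gln *and* the family
expects conversion (ACP, corazonin, MS). Coordinates are 0-based and
half-open everywhere; signal-peptide boundaries are inputs (the crude
`approximate_signal_end()` fallback is labelled approximate). Excised
peptides from Dermaptera CRF-DH precursors carry a low-confidence warning:
their N-terminal cleavage cannot be predicted from sequence alone.

## The AED statistic

For rows $i, j$ of an alignment, sites where either row has `-`, `X` or `?`
are deleted *for that pair only* (pairwise deletion; gaps in amino-acid
alignments carry no substitution information here, so all three characters
are treated alike). With $p$ the fraction of differing remaining sites, the
Poisson-corrected distance is $d = -\ln(1-p)$. AED is the mean of $d$ over
all unordered pairs — the mean of corrected distances, not the correction of
the mean $p$. Pairs with $p = 1$ or no shared unambiguous site are excluded
from the mean with a logged count rather than aborting: merged cross-order
alignments can contain saturated pairs. The standard error is the standard
deviation of replicate AEDs over 500 column resamples (sites drawn with
replacement; the seed is a required argument wherever randomness exists).
Medians over an even number of groups are the arithmetic mean of the central
pair. Published AED values in this field typically come from MEGA, whose
exact sub-options (duplicate handling, uniform rates) are rarely reported,
so cross-checks against published numbers are tolerance-based rather than
exact; within this package the statistic is pinned by a brute-force oracle
test at 1e-12.

## Logos, consensus, ancestral depth

Per column, non-gap residue frequencies give an information content
$I = \log_2 20 - H$ (bits), with letter heights $f \cdot I$; `X`/`?` count as
gaps. No small-sample correction is applied by default so the closed forms in
the tests are exact; `small_sample_correction = TRUE` subtracts the usual
$19/(2 n \ln 2)$ approximation. Consensus emits the plurality non-gap residue
when its fraction reaches the threshold, else a lowercase `x` (ties always
mask), reproducing notation like `PSLSIVNxxDVLRQRxxLExxRxRMR` for the CRF-DH
core.

Ancestral depth is presence/absence reasoning, not tree-based
reconstruction, because that is how such statements are made in this
literature: a candidate peptide found (by exact string match) in a remipede —
or any deeper outgroup such as Myriapoda or Malacostraca, which additionally
sets a `pre_hexapod` flag — is called ancestral for Hexapoda; a silverfish
(Zygentoma) hit gives Pterygota; no outgroup hit but presence in at least
`min_orders` groups gives Polyneoptera. The literature's presence criterion
("found in most orders") is not quantified, so `min_orders` is configurable
and defaults to 5 of the 11 analyzed orders; every call reports the
threshold used. The depth is monotone in outgroup hits by construction.

## The simulator

`simulate_family_set()` assembles an ancestral precursor from a family rule —
signal peptide, optional propeptide/linkers, flank motifs, ancestral core,
amide-donor Gly — and evolves it down a star tree of groups, each group a
star of taxa. Substitution follows a 20-state equal-rates (Jukes–Cantor-type)
model: per site, replacement probability
$\tfrac{19}{20}\left(1 - e^{-\tfrac{20}{19} r t}\right)$ along a branch of
length $t$ with region rate multiplier $r$, target drawn uniformly among the
other residues. This is exactly the model for which the Poisson correction is
the matched estimator (up to its saturation term), so parameter recovery is
an analytic test, not a calibration. With `protect_motifs` (default) the
planted motifs and amide Gly are frozen *and* substitutions never introduce
new Lys/Arg outside them; since ancestral linkers contain no basics, no
spurious cleavage site can ever arise and excision recovers the planted
coordinates exactly — a designed invariant, checked on over 1,000 simulated
precursors. The target restriction perturbs pairwise coincidence
probabilities by under $10^{-3}$, far below test tolerances.

Defaults are the study conditions and are not revisited: 11 polyneopteran
order labels; 5 taxa per group; root-to-group depths between 0.10
(Grylloblattodea) and 0.45 (Dermaptera, Plecoptera) expected
substitutions/site, mirroring the reported ranking of intra-order
conservation, with within-group branch lengths defaulting to a quarter of
the group depth; rate multipliers core 0.05, linker 1.0, signal 1.0; no
indels (an explicit `indel_rate_linker` adds them, in linkers only, keeping
coordinate truth exact); optional `?`-masking to emulate incomplete
transcripts. What the simulator does *not* emulate: realistic indel length
distributions, alignment error (simulated sets are gap-free and already
aligned unless indels are enabled), amino-acid compositional bias,
hydrophobic signal-peptide structure, and rate variation within a region.
Tests passing on simulated data therefore validate the machinery and the
statistics, not the biology of any particular transcriptome.

## Alignment handling

FASTA I/O preserves `?` verbatim (incomplete transcripts are annotated that
way). External alignment is a subprocess hook (`"mafft --auto {in} > {out}"`)
rather than a re-implementation; merging without a hook stacks alignments
with terminal-gap padding, a documented approximation. Whether merged
cross-order alignments should be re-aligned or profile-merged is left to the
user — both paths exist. Peptide columns are selected by mapping each row's
ungapped core coordinates through its gaps and keeping the union of covered
columns, which preserves indels inside peptides.

## Worked example

```{r example}
sim <- simulate_family_set(sim_config(rule_for("CCAP", reg), seed = 42))
rep <- run_family_report("CCAP", split_by_group(sim$sequences), reg,
                         n_boot = 100, seed = 7)
rep
head(rep$per_order[, c("group", "n_precursors", "aed", "se")])
```

The conserved-core signature — peptide-column AED far below precursor AED —
is the package's central readout, and on simulated data it is guaranteed by
the rate multipliers rather than asserted from published values.

## Problem sizes and runtime choices

The shipped tests use 11 groups x 5 taxa per family (1,155 precursors across
the 21 families for the round-trip property), 200-column linker alignments
with 50 taxa for analytic parameter recovery, 200 random alignments up to
8 x 30 for the oracle equivalence, and mostly 25-100 bootstrap replicates
where only determinism or relative ordering is asserted (500 where a
standard error is interpreted). These sizes make the whole suite run in
about a minute while leaving every statistical claim testable.

## Limitations

* Signal-peptide boundaries are inputs; no predictor is bundled.
* Disulfide connectivity (AST-CC, CCAP, trissin Cys pairs) is not modelled.
* pGlu conversion is a flag, not a quantitative estimate (it is only
  partial for myosuppressin in vivo).
* Ancestral calls are exact-match presence logic; no probabilistic
  reconstruction.
* Multiple-copy precursor families (pyrokinins, SMYamide, the multi-copy
  SIFamide variant) and AKH precursors, whose orthology is unresolved across
  these orders, are out of scope.
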