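# peptevo

Comparative analysis of **single-copy neuropeptide precursors**: rule-based
excision of mature peptides from precursor sequences, Poisson-corrected
divergence statistics, consensus/ancestral-sequence assignment, and
sequence-logo computation — with a bundled precursor-evolution simulator so
the whole pipeline is testable end to end without external data.

## Who this is for

Researchers in insect peptidomics and molecular evolution who annotate
neuropeptide precursors from transcriptomes and want reproducible,
scriptable versions of the standard manual steps: locating prohormone
convertase cleavage sites, excising the mature peptide, flagging C-terminal
amidation and N-terminal pyroglutamate, and quantifying how much better
conserved the mature peptide is than its precursor across deep lineages
(e.g. the orders of Polyneoptera: cockroaches, locusts, stick insects and
their relatives).

## What it computes

**Processing grammars.** A registry of 21 single-copy families (ACP,
allatotropin, AST-CC, AST-CCC, CCAP, CCHamide-1/2, CNMamide, corazonin,
CRF-DH, CT-DH, elevenin, HanSolin, MS, NPF-1/2, proctolin, RFLamide,
SIFamide, sNPF, trissin) encodes where each peptide sits in its precursor
and which mono- to tetrabasic Lys/Arg motifs flank it (e.g. CCAP:
KR ... peptide-Gly ... KKR/RKR). Seventeen of the 21 peptides are
C-terminally amidated; AST-CC, elevenin, proctolin and trissin are not.

**Average evolutionary divergence (AED).** For every pair of aligned
sequences, sites with `-`, `X` or `?` in either row are removed (pairwise
deletion), *p* is the fraction of differing remaining sites, and the
Poisson-corrected distance is

    d = -ln(1 - p)

AED is the mean of *d* over all unordered pairs, with a standard error from
500 bootstrap resamples of alignment columns. Per-family reports give
per-order AED, the median across orders, and the overall AED of the merged
precursor alignment versus the mature-peptide columns alone.

**Logos, consensus, ancestral depth.** Per-column information content
`log2(20) - H` with frequency-scaled letter heights; plurality consensus
with `x` masking below threshold; and a presence/outgroup ladder that calls
a peptide ancestral for Polyneoptera, Pterygota (silverfish hit) or Hexapoda
(remipede or deeper hit).

**Simulator.** A 20-state equal-rates substitution model — the generator for
which the Poisson correction is the matched estimator — evolves
grammar-correct precursors down a star tree of orders with conserved cores
(rate x 0.05), fast linkers, frozen cleavage motifs and full coordinate
ground truth.

## Worked example

```r
library(peptevo)
reg <- load_family_rules()

# every family grammar recovers its recorded ancestral peptide exactly
head(golden_peptide_table(reg)[, c("family_id", "core", "length", "amidated", "pglu")], 5)
#>   family_id                core length amidated  pglu
#> 1       ACP          QVTFSRDWNA     10     TRUE  TRUE
#> 2    AST-CC GQQKGRVYWRCYFNAVTCF     19    FALSE FALSE
#> 3   AST-CCC      SYWKQCAFNAVSCF     14     TRUE FALSE
#> 4        AT       GFKNVALSTARGF     13     TRUE FALSE
#> 5      CCAP           PFCNAFTGC      9     TRUE FALSE

# simulate a CCAP family across 11 orders and run the full report
sim <- simulate_family_set(sim_config(rule_for("CCAP", reg), seed = 42))
rep <- run_family_report("CCAP", split_by_group(sim$sequences), reg,
                         n_boot = 100, seed = 7)
rep
#> <family_report> CCAP (11 groups)
#>   median AED 0.11845 | overall precursor 0.48776 | peptide 0.01983
#>   consensus: PFCNAFTGC
#>   ancestral: PFCNAFTGC (Polyneoptera)
```

Reading the numbers: the 55 simulated precursors have drifted substantially
(overall AED 0.49 substitutions/site after correction), yet the excised
CCAP peptide columns are nearly frozen (AED 0.02) — the conserved-core
signature this analysis is built to expose. Relict orders show low
within-order divergence (Grylloblattodea 0.023 ± 0.011) and species-rich
deep orders high divergence (Plecoptera 0.193 ± 0.040), matching how such
groups behave in real data.

A thin CLI over the same functions ships in `inst/scripts/peptevo`
(subcommands `simulate`, `excise`, `aed`, `logo`, `consensus`, `report`).

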