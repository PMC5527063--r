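---
title: "Methods: ceRNA network inference in cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference in cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The model

A competing endogenous RNA (ceRNA) relation posits that a lncRNA and an
mRNA regulated by the same miRNAs compete for those miRNAs: when the
lncRNA is abundant it soaks up shared miRNAs and the mRNA is de-repressed.
`cernet` operationalises this as three testable claims about a candidate
(lncRNA, mRNA) pair across an *ordered* condition series (here: dry
period → early lactation → peak lactation):

1. **Shared regulation.** The pair shares more miRNA regulators than
   expected by chance. With a universe of $N$ miRNAs, of which $K$ target
   the lncRNA, $n$ target the mRNA and $c$ are shared, the tail
   probability is
   $$P = \sum_{i=c}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$
   the probability of at least $c$ shared regulators when the mRNA's $n$
   regulators are a uniform draw from the universe. This is exact and
   assumption-light: its null is independence of the two target sets given
   their sizes, which is also precisely how the package's null generator
   wires edges — making the false-positive calibration checkable.
2. **Differential expression.** All three members respond to the
   condition axis, per the class-specific thresholds below.
3. **Trend opposition.** Over the full condition series, the lncRNA and
   mRNA trend together (identical, not-all-flat direction profiles) while
   at least one shared miRNA shows the exactly mirrored profile. Shared
   miRNAs whose profile *equals* that of both targets contradict the
   sponge mechanism and are dropped from the pair before the check, with
   the pair re-scored at the reduced shared count.

Claim 3 deserves a note: a pair is detected within a specific pairwise
comparison (the period pair in which all members are differentially
expressed), but trend consistency is always judged on the complete
direction profile across all periods. Dynamic trends are a property of
the whole series; judging them on a two-period slice would let a profile
that disagrees elsewhere slip through and would roughly double the rate
of coincidental matches for single-step comparisons.

## Thresholds and defaults

All knobs live in `cerna_config()` and are recorded in the run manifest.

| parameter | default | units | rationale |
|---|---|---|---|
| `mirna_p` | 0.05 | raw p | miRNA DE gate uses unadjusted p (with the fold-change and score gates it is already compound) |
| `mirna_min_abs_fc` | 2 | linear FC | strict: \|FC\| must exceed 2 |
| `mirna_min_score` | 1 | miRDeep2 score | applies to scored (novel) miRNAs; known miRNAs carry no score and pass |
| `gene_q` | 0.05 | BH q | mRNA/lncRNA gate is FDR-adjusted, per comparison and class |
| `cis_window_bp` | 100000 | bp | symmetric, strand-agnostic, boundary inclusive (gap of exactly 100 kb qualifies; overlap counts as gap 0) |
| `trans_min_abs_r` | 0.95 | Pearson r | strict inequality; computed on log2(x+1) where correlation is less dominated by FPKM heavy tails (a `log_scale = FALSE` switch restores linear-scale r) |
| `cerna_alpha` | 0.05 | p | retention gate on the hypergeometric p; `cerna_gate = "q"` switches the gate to the BH value, which is always reported alongside |
| `lnc_min_len` | 200 | nt | mature length, i.e. the sum of exon lengths — the convention coding-potential classifiers use; the genomic span is a defensible alternative but would pass single-exon-equivalent spans the classifiers never see |
| `lnc_min_exons` | 2 | exons | inclusive |
| `lnc_min_cov` | 3 | reads | maximum over samples, inclusive |
| `trend_epsilon` | 0.25 | log2 | half-width of the "flat" band per consecutive-period step; a quarter-doubling is small relative to the 2-fold DE gate, so no DE-relevant change is misread as flat, while replicate noise at realistic levels rarely crosses it |
| `pseudocount` | 1 | abundance | standard for FPKM/TPM-scale data; stabilises log fold changes at low abundance |
| `n_total_mirnas` | table size | count | the hypergeometric universe defaults to the distinct miRNAs in the supplied target table, keeping the statistic auditable; set it explicitly to use a genome-wide universe |

Two genuinely open design points are exposed as switches rather than
silently decided:

- **Coding-potential consensus** (`coding_filter`): `"all"` (default)
  removes transcripts called coding by *all four* classifiers (CNCI, CPC,
  Pfam, PhyloCSF), i.e. one dissenting tool saves a transcript; `"any"`
  removes transcripts called coding by any tool. The two published
  phrasings of this step are mutually inconsistent, so both are provided
  and the active mode is logged.
- **Re-scoring policy** (`rescore`): after a same-trend miRNA is dropped,
  `"c_only"` (default) shrinks only the shared count — the miRNA still
  targets both members, it merely fails the sponge pattern — while
  `"full"` also decrements the degrees $K$ and $n$. Under either policy
  the re-scored p can only grow; the suite asserts this as a regression
  property. The significance gate is applied once, before pruning;
  pruning itself removes pairs only for losing all shared miRNAs or
  failing trend consistency.

## The synthetic-data generator

`simulate_cerna_dataset()` emulates the study design: 3 ordered
conditions × 3 biological replicates; 500 mRNAs, 100 lncRNAs, 200 miRNAs
at desk scale. Abundances are log-normal (baseline log2 mean 5, sd 2 —
median ~32 FPKM with a realistic dynamic range) with multiplicative
log-normal replicate noise (`noise_log2_sd = 0.25`). Planted features
follow random up/down step patterns of 3 log2 units per step; each of the
20 planted ceRNA triplets ties a miRNA's pattern to the sign-flipped
pattern in its lncRNA and mRNA partners. Planting rates for
non-triplet differential expression are the study's own observed DE
fractions — about 3% of mRNAs, 2% of lncRNAs and 5% of miRNAs — and the
mean background miRNA out-degree is 6, matching the study's
predicted-target density of roughly 1% of the gene universe per miRNA.
These defaults are the package's fixed study conditions, not tuning
knobs.

The generator draws everything through R's Mersenne-Twister stream from
a single seed, so a fixed `simulation_spec()` is bit-reproducible.
`simulate_null_dataset()` disables all planting and wires edges uniformly
at random; conditional on node degrees the shared-miRNA count is then
exactly hypergeometric, which is what makes it a proper calibration
control for the pair test. `simulate_sequences()` additionally emits
FASTA pairs in which every wired edge has at least one exact seed site
(reverse complement of miRNA positions 2–8) planted in its target and
every non-edge combination has its sites rejection-sampled away, so the
scanner's edge recovery is exact by construction.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: count-level sampling noise (abundances are
log-normal, not negative-binomial counts; the DE stage is a location
test on log abundances, not a dispersion-modelled GLM), correlated
expression between features other than planted triplets, isoform
structure, mapping and assembly artefacts, G:U wobble or
thermodynamically scored miRNA binding, and the genome-scale imbalance
between the handful of true sponges and hundreds of unrelated DE genes.
On real data the expected consequence is more candidate pairs per true
sponge; the trend-consistency pruning and the explicit universe $N$ are
the main defences, and external tools (real DE results, real
miRanda/RNAhybrid tables) can be spliced in at any stage through the TSV
interfaces.

## Numerical choices

- The hypergeometric tail is summed in log space (`lchoose` with a
  log-sum-exp reduction). Terms outside the support contribute
  $-\infty$ and are dropped; `c = 0` returns exactly 1 and results are
  clipped to $[0,1]$. The suite checks it against exhaustive enumeration
  of all parameter combinations with $N \le 12$, against `phyper`, and
  against urn sampling at larger $N$.
- The built-in DE test is Welch's t on `log2(abundance + 1)` with a
  per-feature variance floor of $10^{-8}$, so identical replicate vectors
  yield $t = 0$, $p = 1$ rather than 0/0. It is a documented stand-in for
  the external count-based tools, kept pluggable: externally computed
  p-values injected via the `pvalues` argument bypass it entirely.
  At $n = 3$ per group the Welch test is slightly conservative, which is
  the right side to err on for a screening gate.
- BH adjustment is `stats::p.adjust(method = "BH")`, applied within each
  comparison and feature class (and within each comparison's candidate
  pair set at the network stage); an independently coded step-up
  procedure serves as the test oracle.
- Determinism: candidate pairs are sorted by (comparison, lncRNA, mRNA)
  before adjustment and export; shared miRNA sets are sorted; all
  positions are 1-based; GTF coordinates stay 1-based inclusive
  end-to-end, which keeps the inclusive 100-kb window rule free of
  off-by-one adjustments.
- Degenerate inputs fail loudly at the boundary where they are
  detectable: negative or non-numeric abundances, duplicated feature
  rows, exons with `end < start`, targets listed under two classes, and
  conditions with fewer than two replicates are errors; duplicate target
  edges are collapsed with a counted warning (edge duplication has an
  unambiguous resolution, expression duplication does not).

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at the generator's default
scale: recovery of planted pairs is measured over 20 simulated datasets
(20 triplets each) and calibration over 100 null datasets; the
hypergeometric oracle checks enumerate all parameters with $N \le 12$
exhaustively and sample 50 parameter sets up to $N = 500$ with $10^5$
urn draws each. These sizes were chosen so the whole suite completes in
minutes on one core while keeping Monte-Carlo standard errors small
relative to the thresholds being verified.

## Known limitations

- The seed-match scanner is deliberately minimal (exact 7-mer, no wobble,
  no free energy, no conservation); it exists so the pipeline is
  exercisable end-to-end without external tools, not as a replacement for
  dedicated target predictors.
- The hypergeometric test conditions on degrees within the
  differentially expressed subnetwork; with a genome-wide universe $N$ it
  becomes anti-conservative, which is why $N$ defaults to the supplied
  table's universe and every run logs the value used.
- Pairs detected in several comparisons are reported once per comparison;
  consumers wanting distinct pairs should deduplicate on
  (lncRNA, mRNA), as `glance()` does for member counts.
- Three conditions give direction profiles of length two; the trend
  machinery generalises to longer ordered series, but "flat" calling via
  a single epsilon becomes cruder as series lengthen.
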