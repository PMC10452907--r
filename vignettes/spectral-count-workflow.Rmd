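---
title: "Spectral-count differential analysis of sequential biofluid samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-count differential analysis of sequential biofluid samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystflow)
```

# The problem and the model

Spectral counting treats the number of peptide-spectrum matches (PSMs)
attributed to a protein in one LC-MS/MS run as a semi-quantitative proxy
for its abundance. In the study design this package targets, a biofluid
(tumor cystic fluid) is sampled sequentially from patients of several
tumor histotypes, each sample is measured in technical replicates, and the
analytical questions are: which proteins are reproducibly present where,
which differ between histotypes, and whether the fluid's composition is
stable across the sequential samples.

The workflow is hierarchical averaging followed by presence logic and
ratio statistics:

* **Normalization.** Run $j$'s counts are multiplied by $\bar T / t_j$,
  with $t_j$ the run's raw total and $\bar T$ the mean of all run totals.
  All runs then carry the same total signal, which removes between-run
  loading/acquisition differences — the only systematic effect spectral
  counting can correct at this level. The mean-total reference keeps
  values on the familiar SpC scale; any other positive reference would
  change results only by a global factor, and every downstream statistic
  (DAve, relative representation, presence) is ratio-based and therefore
  independent of that choice. Normalization is *equivariant* under global
  rescaling of the raw counts (outputs scale by the same factor; per-run
  profiles are invariant).
* **Master lists.** A sample's master protein list is the mean of its
  replicates' normalized counts, a protein absent from a replicate
  contributing 0; histotype lists average the sample master lists the
  same way. Counting absence as zero (rather than averaging over detected
  replicates only) penalizes sporadic identifications and makes the
  master value consistent with the presence logic: a value is positive
  exactly when the protein was seen at least once. The alternative is the
  main behaviour a reanalysis might legitimately flip, which is why both
  averaging steps are isolated in `buildMasterLists()` /
  `averageHistotype()`.
* **Presence.** "Identified in a sample" means present in its master
  list (≥ 1 replicate). A protein is *highly reproducible* (HR) when some
  histotype contains it in every sample — reproducibility is defined at
  the sample level, not the replicate level, because the sequential
  samples (not the technical replicates) are the biological unit.
  Histotype-specific HR proteins are additionally absent from every
  master list of the other histotypes.
* **Differential calling.** For an ordered pair of histotypes with mean
  counts $a, b$:
  $$\mathrm{DAve} = \frac{2(a-b)}{a+b}, \qquad
    \mathrm{DCI} = \frac{(a+b)(a-b)}{2}.$$
  DAve is a bounded relative difference (±2 at on/off extremes); DCI
  weights the same difference by abundance, so a ±0.4 relative change at
  2 counts cannot be called while the same change at 100 counts can.
  Calls require both indexes to clear their thresholds with matching
  sign; thresholds are inclusive (DAve(15, 10) = 0.4 and DCI(15, 10)
  = 62.5 is a call at the defaults). Both statistics are antisymmetric,
  so reversing a comparison flips up/down calls exactly.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `daveThr` | 0.4 | minimum absolute DAve (dimensionless, in [0, 2]); 0.4 ≈ 1.5-fold |
| `dciThr` | 5 | minimum absolute DCI (squared-count units); suppresses low-abundance calls |
| `repCutoff` | 50 | relative-SpC boundary (percent of the per-protein maximum) between up- and down-represented, inclusive |
| `dbThr`, `expThr` | 0.3, 0.15 | inclusive minimum confidence per PPI evidence channel; a pair is kept if *either* channel passes (the two channels are alternative kinds of evidence, not joint requirements) |
| `alpha`, `fdrThr` | 0.05 | ORA significance needs raw p *and* BH-FDR below threshold; use `fdrThr = 0.01` for the stricter network-module variant |

The ORA **universe is an explicit argument**: enrichment probabilities
depend strongly on the background, and defensible choices differ (all
identified proteins, the HR set, a custom compilation). The pipeline
driver uses all identified proteins and queries the set not identified in
every histotype.

# The synthetic generator

`simulateStudy()` emulates the downstream structure of a
three-histotype sequential study — not spectra, peptides or protein
inference. Defaults mirror the target design: histotypes SM/CS/CG with
3/2/2 sequential samples and 2 technical replicates (14 runs); 60 shared
core proteins with mean SpC uniform in 20–200 (the high-abundance
plasma/CSF background); 4/8/19 histotype-specific proteins at 4–20
(tumor-derived, structurally absent elsewhere); 20 planted differential
proteins drawn from the core with fold change 3 in a designated
histotype. Counts are Poisson (optionally negative binomial with
dispersion 0.1), and each (protein, replicate) cell drops out with
probability $1/(1 + (\mu/\mathrm{mid})^{\mathrm{slope}})$ (defaults mid
= 1, slope = 2) — a logistic in log mean abundance that makes
low-abundance identifications sporadic, which is what gives the HR filter
its meaning. Specific-protein absence outside the owner is structural
(mean 0), so their Venn placement is exact by construction; their
all-samples reproducibility is not guaranteed at the low end of the
abundance range, matching real data.

What the generator does **not** emulate — shared peptides and parsimony
grouping, correlated dropout across replicates of a degraded sample,
batch drift between sequential acquisitions, compositional coupling
beyond the fixed total — bounds what passing tests show: they validate
the pipeline's logic and its operating characteristics under the stated
noise model, not performance on any particular real dataset.

`evaluateRecovery()` scores calls against the truth: a called DEP is a
false discovery only if its true means are equal everywhere — planted
fold-change proteins *and* histotype-specific proteins are genuinely
differential, and the sensitivity figure refers to the planted
fold-change tier specifically.

# Numerical and degenerate-case choices

* DAve and DCI are defined as 0 at $a = b = 0$ (call `none`); the case
  cannot arise for HR proteins under absent-as-zero averaging.
* All thresholds are inclusive (`>=`/`<=`), and the boundary cases are
  pinned in the tests (DAve(15,10), experiments score exactly 0.15,
  relative value exactly 50).
* Relative scaling gives every tied maximum 100; a protein with an
  all-zero profile is a validation error (it cannot be HR).
* Normalization refuses runs with zero total; manifests refuse duplicate
  runs and samples mapped to two histotypes; BH refuses p-values outside
  (0, 1].
* Averaged values carry full double precision; rounding (3 decimals)
  happens only when result tables are written.
* Venn region labels are histotype-name tuples joined with `+` in
  first-appearance order, so outputs are deterministic for a given
  manifest.
* The duplicate-accession rule on reading run reports is *sum* (with a
  warning), preserving the run total that normalization depends on.
* Levene's test is mean-centered by default (`center = "median"` gives
  the Brown–Forsythe variant); the ANOVA observation unit is the
  per-protein normalized SpC over the union of the histotype's identified
  proteins, absence as zero — the natural unit for "composition
  stability" when samples share most of their proteome. One-way ANOVA is
  used: the sample is the only factor varying within a histotype.
* The chi-square homogeneity test uses no continuity correction, so a
  4-class × 3-histotype table has df = 6.
* Bubble charts are **area**-proportional (radius ∝ √n), keeping visual
  comparisons honest; up/down sectors start at 12 o'clock.

# Validation scale

The test suite and the acceptance script run entirely on packaged data
and in-code simulation: the bundled 31-protein worked example (expanded
to 7 samples), property checks on matrices of 10–30 proteins, exhaustive
hypergeometric enumeration up to a universe of 12, and parameter-recovery
sweeps of 20 seeds × the default 111-protein/14-run study — sizes chosen
so the whole suite completes in well under a minute while every planted
effect is still comfortably detectable at the default effect sizes.

# Known limitations

* Spectral counting itself: insensitive below a few PSMs, saturating for
  very abundant proteins; the package adds no NSAF/emPAI or
  intensity-based quantification and no missing-value imputation.
* DEP calling is threshold-based by design; no p-values or
  multiple-testing control are attached to DAve/DCI calls.
* With a single patient per histotype, histotype differences and
  patient differences are confounded — the statistics describe the
  fluids compared, not the histotypes in general.
* Pathway membership and PPI edges are file inputs; results inherit
  whatever database version produced them.
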