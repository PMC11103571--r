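---
title: "Quantification methods for isobaric single-cell proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for isobaric single-cell proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpquant)
```

# The problem

Multiplexed single-cell proteomics (SCP) quantifies proteins in individual
cells through isobaric (TMT) reporter ions, with each 18-plex run carrying a
carrier channel (many cells' worth of peptide to lift fragment signal), a
pooled reference channel, a no-cell control channel, and single cells.
Two features dominate the data: *left-censored missingness* — reporter
signal below the detection limit, biased toward low-abundance proteins —
and *batch effects* across the dozens of runs needed for a few hundred
cells. This package implements a quantification workflow built around three
ideas: normalize at the PSM level using the reference channel so batch
effects cancel before any aggregation; control quantification quality on
two axes (within cells, across samples) before statistics; and tune the
imputation down-shift so imputed values do not distort the intensity
distribution that downstream moderated-t statistics assume.

# PSM-level weighted-ratio normalization

For one protein and one sample channel within a batch, let `X = [x_1..x_n]`
be the reporter intensities of the protein's `n` PSMs in that channel and
`R = [r_1..r_n]` the same PSMs' reference-channel intensities. Each retained
PSM contributes a ratio `Xr_i = x_i / r_i`. PSM weights are

    F_i  = (precursor intensity_i × fill time_i)^0.75,
    Fr_i = F_i / Σ_j F_j,

the product being proportional to the ion population sampled for
fragmentation; the 0.75 exponent is the value established for this weighting
in the isobaric-quantification literature and is exposed as
`weight_exponent`. The protein value is the *lower weighted median*: with
`Xs` the ratios sorted ascending and `W` the weights carried along, the
result is `Xs_k` at the smallest `k` whose flanking cumulative weights both
stay at or below one half. Values are then log2-transformed.

Numerical choices:

* **Tie-break.** When a cumulative weight hits exactly one half, two
  adjacent `k` satisfy the defining condition; the smaller is returned, so
  equal weights reduce to the classic median for odd `n` and the lower
  median for even `n`. Cumulative sums are compared with a relative
  tolerance of `1e-9` so that floating-point noise cannot flip the index.
* **Exclusions.** A PSM with a missing target-channel value, or (in
  reference mode) a missing or zero reference value, is excluded from the
  group; a group left empty yields a missing protein value, never an error.
* **Missing weight metadata.** A PSM with missing fill time falls back to
  `precursor^0.75` with a warning; if every weight product is zero or
  missing the group uses uniform weights. The upstream processor is silent
  on these cases, so they are package policy.
* **No-reference designs.** The default fallback (`channel_sum`) divides
  each PSM's target intensity by that PSM's summed reporter signal across
  all non-missing channels, which yields ratios on a common scale across
  PSMs so that a median over PSMs is meaningful. A literal `psm_sum` mode
  (divide by the sum of the group's target-channel intensities) is provided
  for fidelity to the alternative reading of the defining equation, but it
  makes ratios depend on the group's size and is not the default.
* **Output scale.** The protein value is the ratio itself (its weighted
  median), not a reconstructed absolute intensity; whether the original
  desktop implementation multiplies back into an intensity is not
  documented, and a monotone transform of the same statistic does not
  change any downstream test.

Normalization runs within each batch independently; comparability across
batches comes from the reference-channel denominator, not from any
protein-level correction. This keeps observed values untouched by
imputation at normalization time, unlike protein-level batch-correction
approaches that must impute first.

# Quantification quality control

Filtering is two-axis and ordered: sample (cell) columns are filtered first
by the percentage of valid protein values within the column, then protein
rows by the percentage of valid values across the retained columns.
Thresholds are inclusive (`>=`). The cell axis is evaluated against the
full post-identification-filter protein universe rather than any
protein-filtered subset, so the two axes do not interact circularly and the
retained cell count is a function of the cell threshold alone — which is
what makes the wide threshold-table layout (`qc_grid_table()`) readable.

The grid report (`qc_grid()`) evaluates the full cross-product of
thresholds, with per-cell-type median protein variance computed on observed
(pre-imputation) values only, using the `n−1` sample variance and skipping
proteins with fewer than two observed values in a type; variance at each
grid point is computed after both filters at that grid point. One property
worth stating because it is easy to assume wrongly: the retained protein
count is *not* monotone in the cell threshold. Dropping sparse cells raises
the surviving valid fractions, so a stricter cell filter can retain *more*
proteins at a fixed protein threshold; threshold tables computed from real
data show the same pattern. Monotonicity holds along the protein-threshold
axis within each row, and for the cell counts along the cell-threshold
axis.

Control and empty channels participate in the missingness profile and the
cell filter — watching them drop out at a 70 % within-cell threshold is
itself a useful diagnostic — but they are excluded from differential
expression regardless of configuration, as are proteins supported by fewer
than `min_psm_count = 2` PSMs, whose single-PSM quantifications carry
substantial missingness.

# Down-shift imputation

Missing entries are drawn from `Normal(μ − d·σ, (w·σ)²)` with `μ, σ` the
mean and SD of the observed values of the same column (`scope =
"per_sample"`, the default of the desktop tool this emulates; `"global"` is
available because whole-dataset histograms are the usual diagnostic).
`w = 0.3` is the conventional width default; only the down-shift `d` is
tuned in practice, and both assumptions are explicit because the original
description fixes neither. The pipeline default is `d = 1.0`: at the
conventional `d = 1.8` the imputed values form a separate low-intensity
mode when missingness is high, and distribution inspection shows the
distortion disappears once `d ≤ 1.0`, even without quantification QC.

`distribution_report()` quantifies that inspection. Its bimodality flag
fires when both of two conditions hold, each computed from kernel densities
with a deliberately wide bandwidth (0.15 × observed SD) so that sampling
ripples cannot masquerade as structure:

* the imputed mode sits more than one observed-SD below the observed mode
  (`mode_gap_sd > 1`), and
* imputed draws dominate the pooled density at their mode by a wide margin
  (`dominance > 1.75`), i.e. a distinct peak is actually visible rather
  than an imputed mass hidden under the observed left shoulder.

The two conditions are deliberately redundant: on the default synthetic
world the gap statistic is tightly concentrated (≈ `0.92·d/σ` units) but
passes close to 1 at `d = 1.0`, where the dominance statistic is far from
its threshold (≈ 1.0 vs 1.75); at `d = 1.8` both are far past threshold
(gap ≈ 1.7, dominance ≈ 2.7–3.4 across seeds). The conjunction is therefore
stable at exactly the down-shifts where a single statistic would be
seed-sensitive. Observed values are never modified, the imputed mask is
returned explicitly, and draws are reproducible under a seed.

# Differential expression

Per protein, with two groups of sizes `n1, n2` and pooled within-group
variance `s_g²` on `d_g = n1 + n2 − 2` degrees of freedom, the
empirical-Bayes prior `(d0, s0²)` is estimated by moment matching on
`log s_g²` (digamma/trigamma equations, with a Newton inversion of the
trigamma function), the posterior variance is
`(d0·s0² + d_g·s_g²)/(d0 + d_g)`, and the moderated t statistic
`log2FC / (s̃·√(1/n1 + 1/n2))` is referred to a t distribution on
`d0 + d_g` degrees of freedom. If the observed log-variance spread does not
exceed the sampling noise `trigamma(d_g/2)` — as happens with genuinely
homogeneous variances — the prior degenerates to `d0 = ∞` with a warning
and all proteins share `s0²`; this also protects zero-variance proteins
from division by zero whenever `s0² > 0`. q-values are Benjamini–Hochberg
step-up, implemented directly and cross-checked against the standard
implementation in the tests; the significance flag defaults to `q ≤ 0.05`
(the line drawn on volcano plots), with the count under the raw
`p ≤ 0.05` rule logged alongside, since both rules appear in SCP practice.
The moderated-t implementation is validated against the reference
empirical-Bayes implementation (limma) as an independent oracle in the test
suite; DE always runs on the imputed, QC-filtered, single-cell-only matrix,
and the complete (imputed) matrix is used throughout, including prior
estimation.

# Evaluation

`pca_embed()` embeds cells (observations) on the first two principal
components of the centered protein matrix; `cluster_accuracy()` runs
k-means (fixed seed, 10 restarts) on that 2-D embedding and scores the best
agreement with true labels over cluster-to-label assignments (bijective
permutations when `k` equals the number of labels; per-cluster best label
otherwise), so the result is bounded below by the majority-class fraction.
Clustering on the visual embedding rather than the full matrix is a
deliberate stand-in for a grouping-accuracy procedure that the original
description leaves unspecified; it matches what the PCA figures are read to
show, and is configurable by passing any coordinate matrix.

# The synthetic world

`synth_config()` states the simulated experiment once; tests never tune it.
Defaults: 8 TMTpro-18plex batches; per batch 1 carrier (100×), 1 pooled
reference, 1 control (no cell, signal 2⁻⁶ of pooled), and 15 single cells
split between two types; 1000 proteins with base log2 abundance
`Normal(20, 2²)`; per-protein-batch PSM count `1 + Poisson(2)`; PSM-level
(peptide ionization) spread SD 1; batch shift SD 0.5 (log2); per-channel
measurement noise SD 0.3; per-cell efficiency SD 0.2; 20 % of proteins
carry planted log2 fold-changes of ±{0.5, 1, 2}; detection is logistic in
log2 intensity (slope 1 per log2 unit) with its location calibrated by
root-finding *on the realized pre-censoring intensities* so that the
emitted single-cell missingness hits 40 % overall, with the 10 %
low-quality-cell subset calibrated separately to 70 %. Calibrating on the
realized values rather than the theoretical marginal absorbs finite-sample
fluctuation of the batch shifts and leaves only negligible Bernoulli noise
(the emitted rates land within a fraction of a percentage point of target
across seeds). The reference channel carries 5 single-cell equivalents —
the usual multi-cell reference of carrier-based designs — so the ratio
denominator is rarely censored; with a 1-cell reference, denominator
dropout would dominate protein-level missingness and the 70 % cell filter
would sit on top of the *normal* cells' valid-fraction distribution, which
is not what the emulated design looks like. Decoy (3 %) and contaminant
(2 %) protein groups are emitted flagged, so identification filtering is
exercised on every synthetic run, and `emulate_mbr_off()` removes whole
protein-batch blocks at a configurable rate to mimic the loss of
identification transfer between runs.

What the generator does **not** emulate: co-isolation interference and
carrier-induced ratio compression; correlated peptide behavior within a
protein; non-Gaussian intensity noise; retention-time structure; and any
spectrum-level process. A green end-to-end test therefore establishes that
the pipeline's statistics recover planted effects under calibrated MNAR
missingness and batch structure — not that it is robust to interference or
mis-identification. Two further honest caveats: at the default effect sizes
the two cell types are separable even without quantification QC (the
no-QC-versus-QC cluster-accuracy comparison holds as `≥`, usually `1 ≥ 1`,
rather than demonstrating degradation), and cluster accuracy by
construction cannot fall below 0.5 for two balanced groups.

# Pipeline and reproducibility

`run_pipeline()` executes read → identification filter → normalization →
log2 → missingness profile → cell filter → protein filter → minimum-PSM
filter → imputation → DE → volcano/evaluation, writing every stage output
and a count-reconciled summary (`in = out + removed` at each filtering
stage) under the run directory. Configuration is a validated flat list
(JSON on disk; unknown keys are rejected); every default reproduces the
workflow's chosen settings — 70/50 thresholds, `min_psm_count = 2`,
`d = 1.0`, reference-mode ratios, `q ≤ 0.05`. All randomness (synthesis,
imputation, k-means) flows from one top-level seed through fixed named
offsets, so a stage rerun under the same seed is byte-identical. The zero
reporter intensity convention is global: 0 and blank are read as missing,
never as measured zeros, because an isobaric reporter signal of zero means
the ion was not detected.

# Known limitations

* Reporter-ion isotope-impurity correction is assumed already applied;
  the reader defaults to corrected reporter columns (configurable).
* Identification-level FDR is assumed controlled upstream; the package
  only removes flagged groups.
* Only two-group designs are supported in DE; no trend fitting on the
  prior, no multi-factor models.
* The grouping-accuracy procedure is this package's own stand-in (k-means
  on the 2-D PCA embedding), not a reimplementation of any published one.
* The control-channel signal model in the generator is a crude constant
  offset with high censoring; it is there to exercise role handling, not
  to model reagent background faithfully.
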