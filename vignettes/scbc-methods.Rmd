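---
title: "Methods: background modeling, secretion calling and pSI on single-cell barcode chips"
author: "scbcsec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: background modeling, secretion calling and pSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbcsec)
```

## The measurement and its data model

A single-cell barcode chip (SCBC) isolates cells in ~1500 one-nanoliter
microchambers, each carrying an 11-stripe antibody barcode that captures a
panel of secreted proteins over an on-chip incubation window `T2` (hours).
Bright-field imaging counts the cells per chamber; fluorescence scanning
yields one raw intensity (arbitrary units, AU) per analyte per chamber.
After merging, the analysis input is one row per chamber: chamber id, grid
position, cell count and 11 intensities (`read_chamber_table()`).

Occupancy defines the roles: **0-cell chambers measure the assay
background**, **1-cell chambers carry all single-cell statistics**, and
chambers with two or more cells are kept for QC but never enter single-cell
quantities. A typical chip partitions roughly as 300 / 400 / 350 / 200
chambers with 0 / 1 / 2 / 3 cells.

The experimental design splits a fixed total stimulation time `T` into a
bulk priming window `T1` (cells interact in culture under molecular
stimulation) and the chip window `T2 = T − T1` (cells isolated, stimulation
continuing). Sweeping `T1` isolates the contribution of cell–cell
interaction to functional activation.

## Background model and secretion cutoff

For each analyte the background is the per-stripe Gaussian fitted to the
0-cell intensities of the same chip (`fit_background()`; no pooling across
chips, because stripe chemistry and scan conditions vary per chip).
Moment estimates (sample mean `mu`, sd `sigma`) are the default; a
least-squares Gaussian fit to the 20-bin histogram is available
(`method = "histogram"`) to mirror binned-fit practice, and on Gaussian
data the two agree within a few percent. Saturated values are excluded —
they are censored observations, not background draws. The secretion cutoff
is

> cutoff = mu + 2 sigma,

and a single cell is called secreting an analyte when its raw intensity is
**strictly** above the cutoff (ties are measure-zero on real data; the
strict rule makes tests deterministic). Saturated single-cell values are
called positive and flagged.

A one-sample Kolmogorov–Smirnov test against the fitted Gaussian is
attached to every fit. Because the reference parameters are estimated from
the same values, the test is anti-conservative (the Lilliefors effect), so
`ks_p` is **advisory**: the pipeline warns below 0.05 and never gates on
it. Whether the historical analyses ran the KS test on raw values or on the
20-bin histogram is not documented; both are exposed
(`test_normality(on = "raw" | "binned")`, raw default).

Some chips drift across the device. `detect_and_correct_gradient()` fits an
ordinary linear trend of the 0-cell intensities on the row index (column,
or both, by option), and only when the slope is significant at `p < 0.01`
subtracts the centered trend from **all** chambers, so single-cell net
signals face the same correction as the background they are compared to.
The correction is idempotent: a corrected chip shows no significant
residual trend. The axis and threshold are options because the historical
record states only that a gradient "was corrected".

## Net signal, rates, and pSI

For every 1-cell chamber and analyte, net intensity is
`max(raw − mu, 0)` (clamped mean subtraction keeps rates and pSI
non-negative), and the secretion rate is `net / T2` (AU/h), which makes
conditions with different `T2` comparable.

Polyfunctionality `k` is the number of analytes a cell is called positive
for. The polyfunctional strength index stratifies cells by exact `k`:

> psi_k = (n_k / n_cells) × mean over cells with exactly k calls of
> (sum of T2-normalized net rates over their called analytes)

and `psi_total = sum over k >= 1 of psi_k`. The per-analyte decomposition
(`psi_by_analyte()`) is the mean call-gated rate per analyte; it sums to
`psi_total` exactly because both are marginalizations of the same
cell × analyte gated-rate sum. The familiar "1, 2, 3+" figure bins are a
reporting view (`psi_display_bins()`); internal computation never pools.
A raw-AU mode (`use_rates = FALSE`) exists for sensitivity checks.

Two ensemble rate summaries coexist deliberately:

* **call-gated** rates feed pSI (a cell contributes only what it is called
  positive for);
* **ungated** mean net rates over all single cells
  (`per_analyte_mean_rate`) feed fold changes and composition
  (`compare_conditions()`, `secretion_composition()`). Ungated means match
  ensemble "fold above background" comparisons, are independent of
  cutoff-estimation noise, and keep large-fold denominators statistically
  stable. Ratios with a zero denominator are reported undefined, never
  infinite.

Embedding (`embed_and_cluster()`) applies PCA to the cells × analytes rate
matrix after `log1p` (secretion rates are heavy-tailed; switchable),
followed by k-means with a fixed seed. Cluster count is explicit
configuration — no automatic model selection is claimed.

## The synthetic chip generator

Raw chip data for the motivating studies is not publicly deposited, so the
package ships a generator (`generate_chip()`) whose defaults encode the
study-scale conditions, and every pipeline stage is tested against it:

* **Occupancy**: explicit counts (default 300/400/350/200) or Poisson
  loading; chambers laid out row-major and shuffled.
* **Background**: per-stripe Gaussian, exemplar `N(106, 16.2)` AU, with an
  optional linear row gradient (`inject_gradient()` for testing the
  correction).
* **Secretion**: two-layer Bernoulli — a cell is a secretor with
  probability `secreting_fraction`; a secretor secretes each analyte
  independently with probability `analyte_activity`. Per-hour amplitudes
  are lognormal, scaled by `T2`; multi-cell chambers sum independent
  per-cell contributions (no on-chip interaction model is claimed). The
  lognormal family is an assumption: the true on-chip distribution of
  secreted signal is unknown, and is flagged as such in scenario notes.
* **Polyfunctional coupling**: the signal log-mean gains 0.5 log-units per
  additional secreted analyte (on by default), so polyfunctional cells
  carry the highest signals — the empirical motivation for pSI.
* **Detector**: intensities clip at 65535 AU (16-bit scanner) and set the
  saturation flag.

Determinism is strict: identical `(config, condition, seed)` yield bitwise
identical chips, cohorts derive per-condition seeds from the master seed by
a fixed affine map mod 2^31−1, and the caller's RNG state is never touched.

### Calibration: why the secretor probability is not the headline fraction

With 11 analytes each thresholded at `mu + 2 sigma`, a completely silent
cell fires at least one false-positive call with probability
`1 − (1 − q)^11 ≈ 0.22` (`q = P(Z > 2) ≈ 0.0228`). A measured
"fraction of cells with detectable secretion" therefore rides on a ~22%
multiplexed false-positive floor. Setting the generator's secretor
probability equal to a target headline fraction would overshoot the
measured value badly. `calibrate_secreting_fraction()` instead inverts the
exact per-cell call-count distribution — Poisson-binomial true calls plus
binomial false positives — so that the **pipeline-measured** fraction (at
any `min_k`) equals the target. The named scenarios use this inversion:

* `ot1_tetramer_scenario()`: `T = 24 h`, `T1 ∈ {0.2, 4, 16} h`; measured
  detectable fractions calibrated to 23% / 43% / 60% (the last
  extrapolated — only the trend, not a value, is reported for 16 h); the
  4 h IL2 log-mean is solved analytically so the ensemble mean IL2 rate is
  10× its 0.2 h value; CCL3 starts ~10-fold above background and grows to
  occasional saturation.
* `human_cd8_scenario()`: `T = 13 h`, `T1 ∈ {0, 8} h`; measured
  `P(k ≥ 2)` calibrated to 20% and 55%.
* `human_cd4_scenario()`: `T = 13 h`; only a floor (">200-fold" total
  secretion increase) is reported, so the generator is calibrated to an
  expected 300-fold as a representative value above it, with a near-silent
  baseline (secretor probability 0.02, 0.5 AU/h signals).
* `density_sweep_scenario()`: illustrative density-to-fraction mapping;
  no published percentages exist for it.

The analytic mean-rate model behind the signal calibration accounts for
secretor prevalence, per-analyte activity, the coupling factor
`E[e^{0.5(M−1)}]` and the clamped-noise floor `sigma / sqrt(2π) / T2`.

### What the generator does and does not emulate

It reproduces occupancy statistics, per-stripe Gaussian backgrounds,
gradients, saturation, condition-dependent secreting fractions and fold
changes — the features the pipeline's statistics consume. It does **not**
emulate antibody cross-reactivity, spatial cell aggregation dynamics,
contact-feedback kinetics, stripe-to-stripe correlation within a chamber,
or AU-to-molecule calibration. Passing round-trip tests therefore
demonstrates the pipeline's correctness and internal consistency under the
stated generative assumptions, not the biological fidelity of those
assumptions to any particular chip.

## Numerical and statistical choices

* Problem sizes: test and acceptance cohorts use one chip per condition
  (400 single cells, 300 background chambers), the scale of a real chip;
  the KS size/power checks use 1000 and 100 replicates at n = 300.
* At a fitted cutoff, the sampling error of a null per-analyte call rate
  has two parts: binomial `sqrt(q(1−q)/n1)` and a delta-method
  cutoff-estimation term `dnorm(2) · sqrt(3/n0)` (var of `mu + 2·sd` is
  ~`3 sigma²/n0`). Tests and diagnostics use the combined s.e.; with
  n1 = 400, n0 = 300 the two are comparable (0.0075 and 0.0054).
* Sampling spread of headline statistics at study scale: the measured
  detectable fraction at n = 400 has s.e. ≈ 2.8 percentage points
  (binomial plus shared cutoff noise across 11 analytes); the IL2
  ensemble fold estimate has CV ≈ 19%, dominated by the heavy-tailed
  amplitude of a few dozen IL2 secretors. These are properties of the
  chip-scale design, not of the estimators.
* Degenerate inputs: zero-variance backgrounds, undersized 0-cell samples,
  empty call tables, zero fold-change denominators and all-identical
  embeddings are classed errors or defined fallbacks, never silent NAs.
* Boundary rule: `raw == cutoff` is a negative call (strict inequality).

## Known limitations

* pSI here is the fixed per-k definition above; other operationalizations
  (pooled k ≥ 2 thresholds) exist in the literature and would shift
  absolute values, though not the conservation identities.
* No bootstrap confidence intervals for pSI; a natural extension.
* No conversion of AU to molecule counts, no image processing, and no
  in vivo statistics — the pipeline starts at the merged chamber table.
* The default 11-plex panel names are placeholders beyond the five
  analytes the shipped analyses discuss; real panels are config-driven.
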