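---
title: "Methods: segmented IVIM fitting and whole-lesion histogram analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented IVIM fitting and whole-lesion histogram analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The signal model and its assumptions

`ivimhist` models the diffusion-weighted magnitude signal of a voxel as the
two-compartment intravoxel incoherent motion (IVIM) decay

$$S(b) = S_0\left[f\,e^{-b D^*} + (1-f)\,e^{-b D}\right],$$

with tissue diffusivity $D$ and pseudo-diffusivity $D^*$ in mm²/s and the
perfusion fraction $f \in [0,1]$. All computation is done in these internal
units; tables and maps are rescaled only at the reporting surface
($\times 10^{-6}$ mm²/s for diffusivities, percent for $f$), which keeps
exponent arithmetic free of unit mistakes. The conventional apparent
diffusion coefficient (ADC) is the single rate of a monoexponential decay
through the b = 0 and b = 1000 s/mm² signals, computed by the exact
two-point formula $\mathrm{ADC} = -\ln(S_{1000}/S_0)/1000$ — algebraically
identical to a two-point linear log fit, but exact and fast.

The model assumes a static tissue compartment, a vascular compartment with
$D^* \gg D$, and no relaxation-time weighting between compartments: $f$ is
a *signal* fraction, not a blood-volume fraction, and no T2 correction is
applied. Tri-exponential and kurtosis extensions are out of scope.

## The segmented fit

Simultaneous four-parameter biexponential fitting is ill-conditioned at
clinical SNR, so the package uses the stepwise scheme throughout:

1. **$D$ and $f$.** Above a perfusion threshold (default 100 s/mm²; with
   the default six-value scheme b = 0, 50, 100, 150, 600, 1000 s/mm² this
   selects b ∈ {150, 600, 1000}) the perfusion term is treated as fully
   attenuated. Unweighted ordinary least squares of $\ln S(b)$ on $b$
   yields $D$ as the negated slope; the regression line extrapolated to
   the y-axis gives the perfusion-free amplitude $S_\text{int}$, and
   $f = (S_0 - S_\text{int})/S_0$ against the *measured* b = 0 signal.
   Unweighted OLS is deliberate (plain linear regression, no variance
   weighting); using the measured rather than a fitted $S_0$ keeps $f$'s
   definition operational and model-free.
2. **$D^*$.** With $S_0$, $D$ and $f$ fixed, $D^*$ is the single free
   parameter of a bounded Levenberg–Marquardt least-squares fit
   (`minpack.lm::nls.lm`) of the full biexponential over **all** b-values
   (the b = 0 residual is identically zero under this parameterization, so
   including it is harmless and keeps the residual definition uniform).

A small perfusion signal at the lowest retained b-value (150 s/mm²) is not
exactly zero, so the segmented estimates carry a known, small residual
bias: for a noiseless voxel with $D = 0.9\times10^{-3}$,
$D^* = 19\times10^{-3}$, $f = 0.2$, the fit returns
$D \approx 0.920\times10^{-3}$ and $f \approx 0.186$ — the tests pin these
values against an independent `lm()` oracle at machine precision, and pin
the $D^*$ refinement against a dense grid search.

### Numerical choices and degenerate inputs

- **$D^*$ box bounds** default to $[1, 200]\times10^{-3}$ mm²/s with start
  value $10\times10^{-3}$: wide enough to bracket pseudo-diffusion values
  reported for abdominal tumors with margin, tight enough to stop the
  optimizer wandering when $f$ is tiny. An optimum within $10^{-8}$ of a
  bound is flagged `dstar_at_bound`.
- **Identifiability floor** $f < 0.01$: below one percent the perfusion
  term is smaller than quantization noise and $D^*$ is unidentifiable, so
  it is reported missing with flag `f_below_floor` rather than as a
  bound artifact.
- **Clamps.** Negative slopes clamp $D$ to 0 (`clamped_d`); $f$ outside
  $[0,1]$ clamps to the interval (`clamped_f`). Voxels with a non-positive
  signal at a required b-value are excluded entirely
  (`excluded_nonpositive_signal`) and dropped from feature extraction.
  Flags OR together as integer bits per voxel.
- **Convergence**: iteration cap 100, `ftol = ptol = 1e-10`; on
  non-convergence the best iterate is kept (flagged through `nls.lm`'s
  info code only insofar as the bound flag applies — in practice the 1-D
  problem converges in a handful of iterations).
- No spatial regularization or smoothing is applied anywhere: maps are
  strictly voxelwise.

## Whole-lesion histogram features

From each ROI the package computes nine first-order statistics per
parameter, on the **raw voxel values** (binning would only coarsen them):
mean, median, 5th/25th/75th/90th percentiles (linear interpolation between
order statistics, R quantile type 7), skewness (Fisher–Pearson
standardized third moment), kurtosis (**Pearson convention**, normal = 3 —
chosen because reference kurtosis values for these tumors cluster near
2.2, far from the excess-convention 0), and Shannon entropy in bits.

Entropy alone needs a binning rule. The package uses fixed absolute bin
widths per parameter — 10 ($\times10^{-6}$ mm²/s) for ADC and D, 500 for
D\*, 0.5 percentage points for f — so entropy is comparable across lesions
of different sizes and ranges. Two normalizations coexist deliberately:
entropy uses probability-normalized frequencies (they must sum to 1),
while the display/averaging histograms are normalized to their maximum
(peak = 1), which equalizes lesions of different voxel counts when curves
are averaged within a group. All-identical samples have undefined shape
moments (reported `NA`) and zero entropy.

A lesion-size eligibility utility mirrors the clinical inclusion rule:
largest single-slice area ≥ 3 cm² **and** total volume ≥ 6 cm³, thresholds
inclusive (exclusion is stated for strictly smaller lesions). The
slice-inclusion rule used in manual delineation is out of scope; masks are
taken as given.

## Statistics layer

All tests are two-sided. Three and more groups: Kruskal–Wallis
(tie-corrected H, $\chi^2_{k-1}$), then Dunn's z post-hoc on pooled ranks
with tie correction; since it is genuinely ambiguous whether published
post-hoc p-values of this kind are Bonferroni-adjusted or raw, **both are
reported** (`p_value`, `p_adjusted`). Two groups: Mann–Whitney U (exact
for small tie-free samples). Bonferroni families are defined per
parameter across its nine features for two-group screens, and across
pairwise comparisons for Dunn's — both exposed rather than hard-coded.

ROC analysis computes the empirical curve over thresholds midway between
consecutive observed values; the trapezoidal AUC then equals
$U/(n_1 n_2)$ exactly (an identity the tests verify against exhaustive
pair counting, ties counted half). The Youden-optimal cutoff maximizes
sensitivity + specificity − 1; ties break toward **higher specificity**
(fewer false positives in a diagnostic screen), then toward the lower
cutoff. Confidence intervals are DeLong (assumption-light, standard), and
the p-value against AUC = 0.5 is the rank-sum test, which tests the same
hypothesis. Voxelwise Pearson correlations between $f$ and D or ADC can be
restricted to an $f$ band; the default band is 25–40% (where a
methods-vs-discussion discrepancy exists in the source literature for this
band, the Methods value 25–40% wins; the band is configurable). Fewer than
3 surviving voxels or zero variance yield a missing correlation with a
warning — expected for low-$f$ lesions, where almost no voxels reach the
band.

## What the synthetic data emulate — and what they do not

The generator has two tiers, matching the two uses of published group
summaries:

- **Feature cohorts** (`generate_feature_cohort`): case-level feature
  values drawn directly from per-group Normal(mean, between-case SD)
  distributions of the reference table
  (`inst/extdata/tumor_group_stats.csv`, display units). This bypasses
  image synthesis and gives the statistics layer cohorts with exactly the
  published between-case structure. The headline simulation: mean-$f$
  cohorts for neuroblastoma (n = 11, 21.1 ± 1.85%) and Wilms' tumor
  (n = 8, 11.0 ± 0.80%) are ≈ 5 SD apart, so their ROC is perfect for
  essentially every seed — which is the published result this simulation
  reproduces.
- **Imaging cohorts** (`simulate_imaging_cohort`, `generate_phantom`):
  ellipsoidal lesions on a background-padded grid (default semi-axes
  10 × 10 × 4 voxels at 1 × 1 × 5 mm — ~1700 in-mask voxels, comfortably
  above the clinical eligibility thresholds), voxelwise parameters drawn
  around case-level means that are themselves drawn from the reference
  between-case distributions, and within-lesion spreads set from the
  group interquartile ranges (IQR/1.349, a robust SD). Signals follow the
  forward model exactly, then acquire **Rician** magnitude noise
  ($\sqrt{(S+g_1)^2+g_2^2}$, $g_i \sim N(0,\sigma)$) with
  $\sigma = S_0/\mathrm{SNR}$ defined at b = 0 — the natural model for
  magnitude MRI; the default SNR of 50 is typical of abdominal EPI-DWI at
  1.5 T.

Distribution families are an open choice the source summaries constrain
but do not identify: defaults are normal for $D$ and $f$ and
moment-matched log-normal for $D^*$ (strictly positive, right-skewed),
all configurable. Sampling uses redraw truncation into the physical
domain ($D \ge 0$, then $D^* \ge D$ voxel by voxel) rather than clipping,
so no probability mass piles up at the bounds and distorts shape
features; $f$ alone clips at its hard interval $[0,1]$.

The phantoms deliberately do **not** emulate: anatomy, partial-volume and
edema effects, motion or EPI distortion, multi-coil noise correlation, or
acquisition engineering. Passing recovery tests on these phantoms
therefore certifies the *estimator* under the stated noise model, not
robustness to real-world artifacts.

## Reproducibility and problem sizes

A single integer seed governs every stochastic operation; each generator
takes an explicit `seed` argument and restores the caller's RNG stream, so
pipelines are bit-reproducible (`run_pipeline` reruns byte-identically).
The test suites size their simulations to be decisive yet quick: 300
voxels per cell for the SNR sweep (f ∈ {0.05, 0.1, 0.2, 0.3} ×
SNR ∈ {25, 50, 100}), 1000 replicates per test for the type-I-error
checks, 10⁴–10⁵ draws for moment and concentration checks, and an 8-case
demo cohort at SNR 50 for the end-to-end run. These sizes are the
package's own choices for stable assertions; all thresholds were fixed
from the statistics of the quantities being tested, not tuned to runs.

## Known limitations

- The segmented $D$/$f$ estimates carry the residual-perfusion bias
  described above; it shrinks as the perfusion threshold rises, at the
  cost of fewer regression points.
- $f$ is uncorrected for compartmental T2 differences and should be read
  as a signal fraction.
- DeLong intervals degenerate at AUC = 1 (width zero); with n ≈ 10 per
  group this is a statement about the sample, not the population.
- Reference-table entropy and shape-feature magnitudes depend on the
  original binning, which is not published; the package's fixed-width
  rule is internally consistent but not guaranteed to match other
  software's absolute entropy values.
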