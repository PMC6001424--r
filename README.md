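# ivimhist

Intravoxel incoherent motion (IVIM) and ADC histogram analysis of
multi-b-value diffusion-weighted MRI, built for the setting where it has
shown the most diagnostic promise: large, heterogeneous solid abdominal
tumors whose whole-lesion parameter distributions — not just their means —
separate tumor types.

## The problem and the model

Diffusion-weighted MRI signal decays with the diffusion weighting *b*. In
perfused tissue the decay is biexponential (Le Bihan's IVIM model):

    S(b) / S0 = f · exp(−b·D*) + (1 − f) · exp(−b·D)

where *D* (mm²/s) is the tissue water diffusivity, *D\** ≫ *D* the
pseudo-diffusion coefficient of blood moving through randomly oriented
capillaries, and *f* ∈ [0, 1] the fraction of signal from the vascular
compartment. The conventional apparent diffusion coefficient (ADC) collapses
both compartments into a single monoexponential rate,
`S(b)/S0 = exp(−b·ADC)`, fitted here in closed form from b = 0 and
1000 s/mm².

`ivimhist` implements the **segmented (stepwise) fit** that makes the IVIM
parameters stable voxel by voxel:

1. above a perfusion threshold (b > 100 s/mm²) the perfusion term is
   negligible, so ordinary least squares on ln S(b) gives *D* (negated
   slope) and, by extrapolating the line to the y-axis, *f* as the relative
   shortfall of the intercept against the measured b = 0 signal;
2. *D\** alone is then refined by bounded Levenberg–Marquardt least squares
   of the full biexponential model with *D*, *f* and S0 held fixed.

From each whole-lesion ROI the package computes nine first-order histogram
features per parameter map (mean, median, 5th/25th/75th/90th percentiles,
skewness, kurtosis, Shannon entropy in bits), max-normalized histograms for
group averaging, and a statistics layer: Kruskal–Wallis with Dunn's
Bonferroni-corrected post-hoc comparisons, Mann–Whitney U, ROC curves with
DeLong confidence intervals and Youden-optimal cutoffs, and voxelwise
Pearson correlations restricted to an *f* band.

Because no public patient data accompany this application, the package
ships a first-class synthetic-data module: ellipsoidal lesion phantoms with
voxelwise parameter distributions, Rician magnitude noise at a configurable
SNR, and case-level feature cohorts drawn from published per-group summary
statistics of pediatric renal-bed tumors (hepatoblastoma, neuroblastoma,
Wilms' tumor), so every stage of the pipeline is testable end to end.

## Worked example

```r
library(ivimhist)

# forward model: a perfused voxel (D = 0.9e-3, D* = 19e-3 mm²/s, f = 0.2)
p <- ivim_params(S0 = 1000, D = 0.9e-3, Dstar = 19e-3, f = 0.2)
ivim_signal(p, c(0, 50, 100, 150, 600, 1000))
#> [1] 1000.0000  842.1462  761.0587  710.5416  466.2008  325.2557

# a noisy lesion phantom (SNR 50), fitted and summarized
ph   <- generate_phantom(lesion_spec(snr = 50), seed = 42)
maps <- fit_volume(ph$dwi, ph$mask)
ivim_features(maps, ph$mask, case_id = "demo", group = "NB") |>
  dplyr::filter(parameter == "f")
#>   case_id group parameter  feature  value
#> 1    demo    NB         f     mean 17.146
#> 2    demo    NB         f   median 16.756
#> ...                          (f in percent)

# case-level cohorts from the published group statistics, then ROC
cohort <- generate_feature_cohort(c(NB = 11, W = 8),
                                  parameters = "f", features = "mean",
                                  seed = 42)
roc_youden(cohort, value, group, positive = "NB")
#> ROC (positive = NB, n = 11/8): AUC = 1.000 [1.000, 1.000], p = 2.65e-05
#> Youden cutoff = 16.44: sensitivity 100.0%, specificity 100.0%
```

The fitted mean *f* of ~17% sits where the phantom's generating
distribution put it; the ROC output says the simulated neuroblastoma and
Wilms' cohorts, whose mean-*f* group distributions are about five standard
deviations apart, are perfectly separable by a cutoff between them.

An end-to-end driver is available as `run_pipeline(pipeline_config(...))`
(simulate → fit → features → statistics → ROC, fully deterministic under a
seed), or from the shell:

```sh
Rscript inst/cli/ivim.R run --seed 1 --out demo_run
```

## Layout

- `R/` — signal models, synthetic-data generators, segmented fitting,
  histogram features, group statistics, NIfTI/CSV/JSON I/O, pipeline.
- `vignettes/ivim-methods.Rmd` — the methods account: model assumptions,
  parameter defaults, what the simulations do and do not emulate.
- `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (grid search, numerical integration, `lm`, exhaustive
  pair counting).
- `inst/cli/ivim.R` — thin command-line wrapper
  (`simulate | fit | features | roc | run`).
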