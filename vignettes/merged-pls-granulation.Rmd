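---
title: "Merged NIR and process-parameter PLS modelling of fluid-bed granulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merged NIR and process-parameter PLS modelling of fluid-bed granulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbgpls)
```

## The problem

Fluidized-bed granulation (FBG) grows pharmaceutical granules by spraying a
binder solution onto a fluidized powder bed and then drying the bed in the
same chamber. Two critical quality attributes have to be controlled inline:
the granule size distribution (summarized by the volumetric percentiles
Dv10, Dv25, Dv50, Dv75, Dv90, in µm) and the moisture content (loss on
drying, LOD, in %). Near-infrared (NIR) reflectance spectra respond to both:
moisture through the water absorption bands near 1450 and 1934 nm, and
particle size through baseline offset and slope changes caused by
wavelength-dependent scattering.

`fbgpls` implements, as a tested and reusable pipeline, a chemometric
analysis in which 256 NIR absorbances (1081–2122 nm) are *merged* with 17
unit process parameters (airflow rate, atomizing pressure, temperatures,
pressures, PHT humidity channels, runtime, …) into one partial least
squares (PLS1) predictor block of 273 columns. The question the pipeline
answers is whether that merged block predicts the endpoint granule size
better than the spectra alone — within a batch (the last 10 % of a run
predicted from its first 90 %) and across batches (whole unseen batches
predicted from the other batches of a campaign).

## The model

All supervised models are PLS1 regressions `Y = XB + E`, fit by
non-iterative NIPALS with nested coefficient paths (one pass yields the
model for every latent-variable count). Predictors are autoscaled with
statistics learned from the training rows only; the response is centered
but never scaled. Spectra are first corrected row-wise by the standard
normal variate transform (SNV: each spectrum centered and scaled to unit
SD, removing additive offsets and multiplicative scatter). The number of
latent variables is chosen as the smallest count attaining the minimum
cross-validated RMSECV — both too few and too many components degrade
external prediction.

Three cross-validation schemes are provided: leave-one-out, sequential
k-fold (row *i* to fold *i* mod *k* — an interleaved split that
*interpolates* in time), and block k-fold (contiguous blocks, which
respects the time ordering of autocorrelated process data). Sequential CV
selects the component count well but is optimistic about endpoint error;
block CV is conservative and tracks the external endpoint error better.
The package exposes both so the trade-off is measurable
(`cv_plan()`, `block_cv_plan()`).

Prediction quality is summarized by RMSEP together with the standardized
ratios used in spectroscopic calibration: RPD = SD/RMSEP (≥ 1.75 usable,
> 3 excellent), RER = range/RMSEP (> 10), PRL = RMSEP/laboratory error
(≤ 2), and RPIQ = (Q3 − Q1)/RMSEP (> 3), with the laboratory error taken
as the SD of the per-batch endpoint sizes.

## Outlier screening

Campaigns are screened for aberrant batches before modelling, on the rows
that carry LOD measurements:

* **PCA diagnostics** (`fit_pca`): all variables (targets included) are
  autoscaled so variances compare directly; component signs are fixed by
  making each loading's largest entry positive. Kaiser scores
  (`n_variables ×` explained-variance fraction) drive `choose_n_pc()`, a
  modified Kaiser rule that additionally requires the last retained
  component to sit at a scree elbow (its log-eigenvalue drop must exceed
  the median of the later drops). On data with a smooth
  Marchenko–Pastur-like noise tail the "largest qualifying k" clause can
  still walk into the tail, so the *screening* distance defaults to a
  fixed five components (`outlier_screen(n_pc = 5)`), with the rule kept
  as a diagnostic.
* **Mahalanobis distances** in PC-score space, flagged above 3.
* **SIMCA-style p-values**: one-tailed t-statistics of each row's squared
  distance against the non-outlier reference population.
* **BBE-PLS** (`bbe_pls`): backward batch elimination against the pooled
  SNV-spectra → LOD calibration. Each cycle removes the batch whose
  exclusion most lowers the leave-one-out RMSECV, if a one-tailed
  equal-variance t-test on squared CV residuals is significant at
  p < 0.1. The two residual samples compared are the full model's and the
  reduced model's *on the rows both models predict*: including the
  candidate batch's own residuals would bias every cycle towards
  significance, because the argmin candidate is by construction the batch
  with the worst residuals. This pairing choice is isolated in one
  internal function (`bbe_significance`) so the alternative is a one-line
  change. The latent-variable count is re-selected at each cycle
  (refitting is the conservative choice).

## The synthetic campaign generator

The study whose design this package follows deposited no raw spectra, so
every campaign-scale claim is validated on simulated data with the
statistical structure the analysis assumes (`sim_config()`,
`simulate_campaign()`):

* a spray phase followed by a terminal drying phase (spray rate exactly
  zero while drying);
* process parameters as batch setpoints plus AR(1) noise
  (ρ = 0.97) — the autocorrelation that makes the sequential-vs-block CV
  contrast expressible;
* latent moisture that rises during spray and decays during drying, and a
  latent Dv50 that grows at `growth_gain · spray_rate · g(airflow,
  atomization)` with `g = exp(airflow_effect·z_air +
  atomization_effect·z_atom)`; the other percentiles are fixed span
  factors (0.45/0.7/1/1.4/1.9 × Dv50), which preserves the Dv ordering by
  construction;
* spectra built from a size-dependent baseline (offset plus wavelength
  slope), fixed formulation bands, moisture-scaled Gaussian water bands at
  1450/1934 nm, per-row multiplicative scatter and additive noise;
* two mechanisms that mirror why merging helps on real lines: a per-batch
  lognormal perturbation of the spectral size-response gain
  (`response_sd`, probe/window optics differing between batches — this is
  what breaks purely spectral calibration transfer across batches), and
  state-responsive parameters (bed pressure drop tracking granule size,
  product temperature tracking bed moisture) that carry
  instrument-independent size information;
* sparse LOD measurements (~12 rows per batch) with small gravimetric
  error;
* injectable outlier batches (`inject_outlier_batch`): a ±3-SD shift of a
  fixed parameter subset plus a baseline slope and a distorted
  water-band response, so the corrupted batch is simultaneously a
  PC-space outlier and a regression outlier in the LOD calibration.

Setting `airflow_effect = atomization_effect = 0` switches off *all*
parameter–granule coupling: growth no longer depends on parameters, the
state-responsive terms and the parameter-driven baseline nuisance are
disabled. Because runtime is itself a process parameter, the fully
decoupled configuration also freezes growth (`growth_gain = 0`) in the
null-hypothesis tests — any time-driven size trend would couple the
parameter block to the target through runtime alone.

### What the generator does and does not emulate

It reproduces the *statistical* structure: phase schedules, autocorrelated
parameters, size- and moisture-driven spectra, batch-level calibration
transfer failure, sparse reference measurements, extreme-settings outlier
batches. It contains no granulation physics (no population balance, no
droplet model), the spectral line shapes are idealized Gaussians, and the
parameter ranges beyond the documented airflow window (18.7–36.0 m³/h)
are plausible values for a lab-scale unit rather than measured ones.
Passing tests therefore demonstrate that the *pipeline* recovers known
structure under realistic noise — not that any particular real campaign
would yield the same numbers.

### Problem sizes used in the test-suite and acceptance runs

Full-length batches (the generator default of 2000–3000 rows) make the
campaign suites needlessly slow without changing what they measure, so the
campaign-scale validations use 150–240-row batches. The per-step rates are
scaled accordingly: the moisture dynamics scale with phase length inside
the generator, and the campaign tests raise `growth_gain` to 0.05 so a
short batch traverses the same ~150–450 µm trajectory a full-length batch
does at the default 0.008. The CV-scheme comparison uses
`spray_fraction = 0.88`, the geometry where the endpoint window spans the
spray-to-dry transition and CV optimism matters most. Replicate counts
(20 seeds for recovery properties) match the suite's statistical claims.

## Evaluation designs

* `ma1_split()`: external test = last ⌊n/10⌋ rows; internal test = every
  10th of the leading rows; the rest train. `ma1add_split()` instead holds
  out the last half of the terminal zero-spray run.
* `ma2_folds()`: across-batch folds in campaign order — 9 train/3 test,
  leave-one-batch-out (11/1), and 8/4.
* `run_comparison()` evaluates any approach over the predictor sets
  `nir` (256 SNV channels), `pars` (17 parameters) and `merged`
  (273 columns; optionally 274 with the 7-point moving-average spray
  rate), selecting the component count per fit on training rows only.
  Test rows never contribute to scaling, selection or coefficients.
* `paired_rmsep_test()` compares two models' per-batch RMSEPs with a
  one-tailed paired t-test. Identical vectors return p = 0.5 by
  definition (no evidence either way); a constant nonzero difference is a
  degenerate-test error.
* `coefficient_importance()` averages absolute scaled regression
  coefficients over fitted merged models and ranks the parameters against
  the spectral mean + 2 SD margin.
* `lod_holdout()` rebuilds the sparse moisture calibration: pooled LOD
  rows, every fifth row held out (so 150 rows give the 120/30 split),
  NIR-only PLS with LOO selection.

## Numerical choices

Sample SD (n − 1 denominator) is used everywhere, declared once. SNV
requires at least two distinct values and errors on constant spectra. The
moving average truncates its window at the series edges. Autoscaling
refuses zero-variance columns at the API surface (no silent epsilon
fixes); inside compiled CV folds a column that degenerates within a fold
is centered to zeros instead, since a fold must never abort a whole
search. Latent-variable ties are broken towards the smaller count
(tolerance 1e−12). UVE's cutoff grid is 20 linearly spaced values whose
maximum is the `(n_lv + 2)`-th largest absolute stability (the alternative
"overall maximum" reading is selectable), with cutoff 0 prepended so the
full model always remains a candidate; RMSECV ties go to the smaller
cutoff. The interchange CSVs are written with shortest-round-trip doubles
and parsed with base R's correctly rounded reader, making write → read
bit-exact.

## Known limitations

PLS1 only (one response at a time; no PLS2, kernel or orthogonal
variants). The generator's linearity means PLS is close to the true model
class — real spectra are less kind. SIMCA p-values use a plain t
construction on squared distances (log-distance and pooled-variance
variants are not implemented). The probability-based "jump-degree" outlier
score seen in some screening workflows is out of scope. The pipeline
entry point is the `run_pipeline()` function plus a thin Rscript wrapper
(`inst/scripts/fbgpls-pipeline.R`); the package deliberately ships no
compiled standalone executable.
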