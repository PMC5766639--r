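---
title: "Simplified perfusion fraction from three-b-value DWI: models, fitting and grading statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplified perfusion fraction from three-b-value DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spfmri)
```

## The problem

Gliomas are graded histopathologically, but microvascular proliferation —
the hallmark of high-grade tumors — also leaves a measurable imprint on
perfusion-sensitive MRI. Two established ways to measure it are
intravoxel incoherent motion (IVIM) modelling of multi-b-value
diffusion-weighted imaging (DWI), which needs many b-values and a
nonlinear fit, and dynamic contrast-enhanced (DCE) MRI pharmacokinetics,
which needs intravenous contrast. The *simplified perfusion fraction*
(SPF) sits between them: it estimates the perfusion-linked share of the
DWI signal from only three b-values (0, a low/high cutoff, and a top
value), with no contrast agent and no iterative fitting.

This package implements the SPF computation together with the reference
methods it is validated against (IVIM, extended Tofts DCE), the hot-spot
ROI protocol used to read parametric maps, and the complete two-group
statistical pipeline used for grading — plus synthetic phantoms and
cohorts so that every stage is testable with no external data.

## Signal models

**DWI.** The IVIM biexponential model describes the voxel signal at
diffusion weighting $b$ (s/mm²) as

$$S_b = S_0\left[f e^{-b D^*} + (1-f) e^{-b D}\right],$$

with tissue diffusion coefficient $D$ (mm²/s), pseudodiffusion
coefficient $D^* > D$ driven by capillary blood motion, and perfusion
fraction $f \in [0,1)$. A two-point monoexponential ADC between b-values
$b_{low} < b_{high}$ is

$$\mathrm{ADC}_{low,high} = \frac{\ln(S_{low}/S_{high})}{b_{high}-b_{low}}.$$

Because pseudodiffusion decays an order of magnitude faster than
diffusion, $\mathrm{ADC}_{0,200}$ mixes perfusion and diffusion while
$\mathrm{ADC}_{200,1000}$ is essentially diffusion-only. Their difference
$\mathrm{ADC}_{perf}$ and ratio

$$\mathrm{SPF} = \frac{\mathrm{ADC}_{0,200} - \mathrm{ADC}_{200,1000}}{\mathrm{ADC}_{0,200}}$$

form the simplified perfusion fraction. In the limit where the perfusion
compartment has fully decayed by the cutoff ($D^* b_{cut} \gg 1$), SPF
has the closed form $-\ln(1-f) / (-\ln(1-f) + b_{cut} D)$, implemented in
`spf_infinite_dstar_limit()` and used as an analytic oracle throughout
the test suite.

**DCE.** Tissue concentration under the extended Tofts model is

$$C_t(t) = v_p C_p(t) + K^{trans}\!\!\int_0^t C_p(\tau)\,
e^{-K^{trans}(t-\tau)/v_e}\,d\tau,$$

with transfer constant $K^{trans}$ (min⁻¹), interstitial fraction $v_e$
and plasma fraction $v_p$; $C_p$ is the arterial input function (AIF).
The extended (three-parameter) form is used because $v_p$ is one of the
reported parameters; the clinical software whose output it mirrors does
not document its exact variant, so this choice is recorded as an
assumption. AIF extraction from images is out of scope; a supplied curve
is always used, by default `population_aif()` — a documented biexponential
bolus $A(e^{-m_2 u} - e^{-m_1 u})$ with onset 0.1 min, wash-in
$m_1 = 6$ min⁻¹, washout $m_2 = 0.25$ min⁻¹, peak 5 mM, sampled every
5 s over 4 min to mirror a typical ~4-minute DCE acquisition.

## Numerical choices

* **Convolution.** The Tofts integral is evaluated by *exact* convolution
  of the piecewise-linear AIF with the exponential kernel (a recursive
  update with closed-form segment integrals). This is exact to machine
  precision for a constant input — plain trapezoid quadrature at the
  documented 0.01-min step misses the 10⁻⁶ relative-error requirement by
  a factor of two, which is why the exact scheme replaced it. Small
  $k\,\Delta t$ falls back to a series-safe trapezoid limit.
* **Units.** All diffusion coefficients are carried in mm²/s and rates in
  min⁻¹ internally; the conventional clinical rendering (×10⁻³ mm²/s,
  percent SPF) appears only in printing and reports. The cohort
  generator is the exception: it works in reporting units because its
  calibration inputs are printed in them.
* **Negative values.** Noise can make $\mathrm{ADC}_{perf}$ (hence SPF)
  negative. Values are retained unclipped, with a `negative_perf` flag,
  so that downstream statistics stay unbiased; voxels with non-positive
  signal are masked rather than floored.

## Fitting

**SPF** (`compute_spf()`) uses exactly the three named b-values (0,
`b_cut` = 200, `b_max` = 1000) — the three-b-value reading taken
literally. Log-linear regression over all b-values in each range is
available as an explicitly non-default `method = "range_regression"`.

**IVIM** (`fit_ivim()`) is segmented: $D$ and the high-b intercept by
log-linear least squares over $b \ge b_{cut}$, $f$ from the intercept
deficit relative to $S(0)$, then $D^*$ by bounded one-dimensional search.
Bounds: $0 \le f \le 0.7$, $10^{-5} \le D \le 4\times10^{-3}$,
$D < D^* \le 0.5$ mm²/s. A full bounded nonlinear refinement initialized
at the segmented solution is **on by default**: the pure segmented pass
is biased whenever the perfusion compartment has not fully decayed at
the cutoff (at $D^* = 5\times10^{-3}$ mm²/s the residual perfusion
signal at $b = 200$ biases $D$ by ~5%), and the refinement removes this
at negligible cost. `refine = FALSE` restores the plain segmented
estimator. The fitter is validated against an exhaustive 200³
grid-search least-squares oracle with $S_0$ profiled out analytically.

**Extended Tofts** (`fit_tofts()`) is bounded nonlinear least squares
($0 \le K^{trans} \le 2$, $0 < v_e \le 1$, $0 \le v_p \le 0.3$) with
three fixed starts, keeping the best residual. The residual surface has
a ridge where large $K^{trans}$ with tiny $v_e$ mimics the plasma term
$v_p C_p$; a nested-model guard therefore also solves the plasma-only
model (linear in $v_p$) and prefers it whenever it fits at least as
well. Noiseless recovery is better than 1% across the tested
3×3×3 parameter grid.

## Hot-spot ROIs

`extract_hotspot()` scans every candidate center whose in-plane circular
disc lies fully inside the tumor mask and returns the disc with the
extreme mean (maximum for perfusion-type maps, minimum for
diffusion-type). Discs are two-dimensional because the emulated
acquisition uses 5-mm slices with a 1-mm gap: a 3D sphere would be
strongly anisotropic and slices are effectively independent. The default
radius is 5 mm — the source protocol never states an ROI size, so the
radius is a configurable parameter and radius sensitivity is part of the
test suite. If no disc fits, the radius shrinks one in-plane voxel step
at a time (logged). Ties are broken by the first center in scan order.
Necrosis/cyst/vessel avoidance is the mask's responsibility, not this
module's. `propagate_roi()` re-evaluates the same disc on another map,
mirroring the protocol of propagating SPF ROIs onto IVIM and DCE maps.

## Grading statistics

`grading_report()` assembles, per parameter: group medians and IQRs, the
Mann-Whitney p-value, ROC analysis, and leave-one-out cross-validated
accuracy; plus a pairwise DeLong p-value matrix. Component choices:

* **Mann-Whitney** is exact (full enumeration) when $n_1+n_2 \le 12$
  with no ties, otherwise a tie-corrected normal approximation with
  continuity correction. The continuity term is clamped so that a
  statistic exactly at its null mean yields $p = 1$.
* **ROC** AUC uses the rank method (identical to $U/(n_1 n_0)$ with tie
  halving); the direction is auto-oriented so AUC ≥ 0.5 and recorded.
  Thresholds maximize the Youden index over mid-gap candidate cuts;
  Youden ties favor the more specific cut, matching the reporting
  convention in which diffusion parameters grade with "≤" and perfusion
  parameters with ">" rules. Mid-gap cuts (rather than observed values)
  are used because they are the only convention under which a held-out
  value falling inside a separation gap is classified by the gap's
  middle — which in turn is what makes leave-one-out cross-validation of
  a perfectly separated cohort achieve accuracy 1. The cost is that
  thresholds map exactly through affine, not arbitrary monotone,
  transforms; AUC, sensitivity and specificity are invariant under any
  strictly increasing transform.
* **LOOCV** re-estimates the Youden threshold (and direction) on every
  training fold — the protocol is an interpretation, since the source
  only states that LOOCV "was applied"; a fixed-threshold variant is
  available via `method = "fixed"`. Apparent (same-data) sensitivity and
  specificity are reported alongside, clearly labelled, because it is
  ambiguous which of the two the reference tables contain.
* **ICC** is fixed to ICC(2,1): two-way random effects, absolute
  agreement, single measure. When duplicate reader columns are present,
  downstream statistics use the per-subject mean of the two readers.
* **DeLong** uses placement-value covariances; identical predictors are
  reported as exactly degenerate ($\Delta = 0$, $p = 1$, flagged).

## The synthetic world

`make_dwi_phantom()` draws Rician noise (Gaussian noise on two
quadrature channels, then magnitude) of scale $S_0/\mathrm{SNR}$ around
the IVIM forward signal; `make_dce_phantom()` adds Gaussian noise in
concentration space. Rician for magnitude DWI and Gaussian for derived
concentrations is standard physics; neither is stated by the source.

`make_cohort()` draws per-group, per-parameter log-normal values
calibrated by `lognormal_from_median_iqr()`: $\mu = \ln(\text{median})$,
$\sigma = \ln(q_3/q_1)/(2 \times 0.67449)$, where 0.67449 is the
standard-normal upper quartile. The log-normal family was chosen because
all eight parameters are positive and the reference IQRs are
right-skewed. Two honest limitations of this calibration:

1. A two-parameter family can match the median and the quartile *ratio*
   exactly, but not both endpoints of an IQR that is not geometrically
   symmetric about its median. For the high-grade SPF cell
   (23.56, IQR 21.73–31.49) the calibrated distribution's true quartiles
   are 19.6 and 28.4. The tests therefore assert exactness of the median
   and of $q_3/q_1$, not of the endpoints.
2. The low-grade $v_e$ cell has an extremely wide IQR (0.023–0.228
   around a median of 0.132), i.e. $\sigma \approx 1.7$ on the log
   scale. At group sizes 19/31 the sample-median ordering of $v_e$
   between grades flips in roughly one seed in five — a property of the
   stated group distributions, not a generator defect. The group-ordering
   test requires the joint ≥95% property for the other seven parameters
   and a clear majority for $v_e$.

Parameters are drawn independently by default; a Gaussian copula
(`rank_correlation`) can couple them *within each group* at a specified
Spearman correlation, converted to the latent Pearson scale by
$2\sin(\pi\rho/6)$. Because the two groups have different marginals, the
pooled between-group correlation exceeds the within-group target; the
coupling is exposed as a user parameter rather than asserted, since the
true inter-parameter correlation structure is unknown beyond a few
reported pooled coefficients.

What a green synthetic test does **not** establish: the phantoms have no
anatomy, no partial-volume mixing, no motion or eddy distortions, no
T1/relaxivity signal-to-concentration step, and the cohort draws are
(by default) independent across parameters. Cohort-level results
validate the statistical pipeline against the stated group
distributions, not the clinical claim itself.

## Degenerate inputs and error policy

Constructors reject invariant violations by naming the violated
constraint ($f \ge 1$, $D^* \le D$, $v_e + v_p > 1$, non-increasing
b-values, ...). Fitters mask voxels rather than guessing: non-positive
signals, non-converged fits and $\mathrm{ADC}_{0,200} \le 0$ (SPF
undefined) all produce masked voxels with flags. A constant DWI series
fits as $f = 0$ with $D$ at its lower bound, flagged. An all-zero DCE
curve returns zero parameters, flagged. Masked voxels serialize as NaN
in NIfTI output and restore as masked.

## Known limitations

* NIfTI support is a minimal built-in NIfTI-1 reader/writer (none of the
  target environment's R packages provide one): single-file `.nii`
  (`.gz` supported), diagonal sform only, no reorientation, affines
  beyond voxel size are not preserved.
* No motion/eddy correction, denoising, kurtosis modelling (the scheme
  deliberately caps at b = 1000 s/mm² to avoid kurtosis effects), AIF
  extraction, bolus-arrival estimation, tumor segmentation or
  registration.
* Configuration files are JSON, not YAML.

## A minimal end-to-end run

```{r, eval = FALSE}
classes <- list(
  tissue_class("tumor", ivim = ivim_params(0.15, 0.9e-3, 12e-3),
               extent = list(x = 4:9, y = 4:9, z = 1)),
  tissue_class("normal", ivim = ivim_params(0.04, 1.2e-3, 8e-3),
               extent = list(x = 1:3, y = 1:12, z = 1)))
ph <- make_dwi_phantom(classes, snr = 80, seed = 8, dims = c(12, 12, 1))
maps <- fit_volume(ph$volume, ph$scheme, mask = ph$mask, method = "spf")
extract_hotspot(maps$SPF, mask = ph$class_map == 1, radius_mm = 1.5)

tab <- make_cohort(seed = 1)          # 19 low / 31 high, calibrated
grading_report(tab)
```
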