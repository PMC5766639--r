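# spfmri

Perfusion estimation from diffusion-weighted MRI with as few as **three
b-values**, for grading gliomas — plus the reference methods it is
validated against and the full statistical pipeline, all testable on
synthetic data.

## The problem and who this is for

High-grade gliomas are more vascular than low-grade ones. Perfusion can
be imaged with dynamic contrast-enhanced (DCE) MRI, which requires
intravenous contrast, or with intravoxel incoherent motion (IVIM)
modelling of multi-b-value diffusion MRI, which requires long
acquisitions and a nonlinear biexponential fit. The **simplified
perfusion fraction (SPF)** needs only three diffusion weightings and two
logarithms. This package is aimed at quantitative-MRI researchers who
want a complete, reproducible reference implementation of that pipeline:
signal models, voxelwise fitting, hot-spot ROI reading, and the
two-group grading statistics, with calibrated simulators standing in for
patient data.

## The core quantities

With `S_b` the DWI signal at weighting `b` (s/mm²), a two-point apparent
diffusion coefficient is `ADC_low,high = ln(S_low / S_high) / (b_high −
b_low)`. Using the three b-values 0, 200 and 1000:

```
ADC_perf = ADC_0,200 − ADC_200,1000        (perfusion component)
SPF      = ADC_perf / ADC_0,200            (its fractional share)
```

The reference models are the IVIM biexponential
`S_b = S0 [ f exp(−b D*) + (1 − f) exp(−b D) ]` and the extended Tofts
model `C_t(t) = v_p C_p(t) + Ktrans ∫ C_p(τ) exp(−Ktrans (t−τ)/v_e) dτ`.
Grading uses Mann-Whitney tests, ROC analysis with Youden-index
thresholds, DeLong AUC comparisons, leave-one-out cross-validation,
ICC(2,1) reader agreement and Bonferroni correction.

## Worked example

Forward-simulate a tumor-like voxel on the default 10-b-value scheme,
then recover SPF and the IVIM parameters:

```r
library(spfmri)
s <- dwi_series(default_bvalue_scheme(),
                ivim_signal(ivim_params(0.12, 1.0e-3, 12e-3),
                            default_bvalue_scheme()$b_values, S0 = 100))
compute_spf(s)
#> SPF components (b_cut = 200, b_max = 1000, three_point):
#>   ADC_0_200    = 1.564 x10^-3 mm^2/s
#>   ADC_200_1000 = 1.019 x10^-3 mm^2/s
#>   ADC_perf   = 0.5454 x10^-3 mm^2/s
#>   SPF        = 34.87%
fit_ivim(s)
#> IVIM fit (segmented + refined): f = 0.12, D = 0.001, D* = 0.012 mm^2/s, S0 = 100
```

The low-b decay (perfusion plus diffusion) is half again as steep as the
high-b decay (diffusion only); SPF is that excess as a fraction. The
IVIM fit recovers the generating parameters exactly on noiseless data.

Simulate a calibrated 19-low / 31-high cohort and grade it:

```r
tab <- make_cohort(seed = 1)
grading_report(tab)
#> Grading report (positive class: high )
#>   ADC_0_1000   low 1.299 (1.164-1.406)  high 0.9983 (0.9038-1.244)  p=0.00182  AUC=0.766  thr <= 1.065  sens=0.581 spec=0.947  LOOCV=0.720
#>   SPF          low 10.26 (7.589-13.79)  high 23.86 (19.77-28.63)  p=2.75e-08  AUC=0.973  thr > 16.32  sens=1.000 spec=0.895  LOOCV=0.940
#>   f            low 4.194 (3.441-5.384)  high 8.358 (7.065-11.76)  p=2.26e-07  AUC=0.941  thr > 6.332  sens=0.871 spec=0.947  LOOCV=0.840
#>   ...
```

Each row mirrors a clinical summary table: group medians with IQRs, the
Mann-Whitney p-value, the ROC AUC with its Youden-optimal threshold and
direction (diffusion parameters grade with "≤", perfusion parameters
with ">"), apparent sensitivity/specificity at that threshold, and the
cross-validated accuracy. SPF separates the groups best in this draw —
the behaviour the calibrated generator is built to emulate.

## Command line

```sh
SPFMRI_CLI=$(Rscript -e 'cat(system.file("cli/spfmri", package = "spfmri"))')
Rscript $SPFMRI_CLI simulate dwi --out sim/ --seed 9 --snr 40
Rscript $SPFMRI_CLI fit-dwi --in sim/dwi.nii.gz --bval sim/dwi.bval \
        --method spf --b-cut 200 --mask sim/mask.nii.gz --out-prefix sim/sub01_
Rscript $SPFMRI_CLI hotspot --map sim/sub01_SPF.nii.gz --mask sim/mask.nii.gz \
        --radius-mm 5 --mode max --out sim/roi.json
Rscript $SPFMRI_CLI simulate cohort --out sim/cohort.csv --seed 4
Rscript $SPFMRI_CLI cohort-stats --table sim/cohort.csv --out sim/report
```

Every run writes its resolved configuration as JSON next to its outputs;
identical config + seed gives bit-identical outputs.

## Layout

- `R/` — signal models, DWI/DCE fitting, hot-spot ROIs, cohort
  statistics, synthetic data, NIfTI/CSV/JSON I/O and the CLI.
- `inst/extdata/glioma_cohort_calibration.csv` — the per-group
  median/IQR table calibrating the cohort generator.
- `vignettes/spf-glioma-grading.Rmd` — models, assumptions, numerical
  choices, design decisions and limitations.
- `tests/testthat/` — unit, property and acceptance tests (closed-form
  oracles, brute-force enumerations, grid-search references).
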