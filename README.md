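# aerolung

Aerated-lung volumetry by seeded region growing for longitudinal murine
micro-CT.

In transgenic models of disseminated lung adenocarcinoma (e.g. SPC-raf
mice), tumours are multifocal and diffuse — there is no single nodule to
segment. What *can* be segmented reliably is the aerated lung: air-filled
parenchyma at strongly negative Hounsfield units. As tumour consolidates
lung, the aerated volume falls, so the segmented aerated volume is an
inverse surrogate for tumour burden. `aerolung` implements that workflow
end-to-end for imaging scientists and preclinical researchers, exercised
entirely on synthetic thorax phantoms with exact ground truth:

* **phantoms** — Hounsfield-calibrated synthetic thoraces (body, lungs,
  airway, bone, spherical tumour nodules) with exact label ground truth,
  plus longitudinal cohort simulation;
* **segmentation** — seeded 3D region growing with a percent-of-range
  tolerance, automatic seed placement, overspill (leakage) diagnostics,
  seed repositioning, and the triplicate-averaging protocol;
* **quantification** — voxel-to-mL volumetry, burden surrogates, cohort
  tables (CSV), NIfTI-1 / JSON / YAML plumbing;
* **kinetics** — repeated-measures mixed ANOVA over selected months, a
  late-window group contrast, and the linear growth model fit;
* **dosimetry** — cumulative radiation dose bookkeeping for repetitive
  scanning.

## The method in brief

Given seed voxels with mean HU $r$, tolerance fraction $t$ (default
0.02) and volume HU range $R$, region growing accepts voxels connected
to a seed through the window

$$W = [\,r - tR,\ r + tR\,],$$

using 6-face connectivity by default. Each scan is segmented three times
from independent automatic seedings of 20–40 seeds and the volumes are
averaged. A mask that reaches the grid boundary or exceeds 60% of the
grid is flagged as overspill; the offending seeds are resampled from the
aerated HU window ($[-900, -300]$) and the scan re-grown.

Longitudinal decline of the aerated volume in the tumour-bearing arm is
summarised by ordinary least squares,

$$V(\text{month}) = a + b\,(\text{month} - 1),$$

with generating defaults $a = 0.315$ mL, $b = -0.01$ mL/month in the
cohort simulator, and by a split-plot repeated-measures ANOVA (group,
time, group×time) with complete-case handling of missing follow-up.
Cumulative dose is `n_exams × 202 mGy`.

## Worked example

```r
library(aerolung)

# a mid-disease phantom: 35% of lung voxels replaced by tumour nodules
ph <- make_thorax_phantom(phantom_spec(noise_sd_hu = 0, rng_seed = 101), 0.35)
ph$truth$aerated_volume_ml
#> [1] 0.299864

# triplicate seeded region growing
trip <- triplicate_volume(ph$volume)
trip
#> <triplicate_result> mean 0.2996 mL (SD 0.0000)

# seeds dropped into the airway leak out of the animal ...
bad  <- auto_place_seeds(ph$volume, 10, hu_window = c(-1005, -995), rng_seed = 5)
rep1 <- region_grow(ph$volume, bad)
rep1$overspill$codes
#> [1] "boundary_contact" "excess_volume"

# ... and repositioning into aerated lung repairs the segmentation
fixed <- reposition_seeds(bad, rep1, ph$volume, rng_seed = 6)
region_grow(ph$volume, fixed)
#> <segmentation_report> 0.2996 mL (37451 voxels), window [-684.0, -616.0] HU
```

The measured 0.2996 mL against a ground truth of 0.29986 mL is a 0.1%
error; the report's acceptance window is the 2%-of-range interval around
the pooled seed mean.

Longitudinal statistics on a simulated cohort (9 transgenic, 3 wildtype,
months 2, 4, 6, 7–13):

```r
tab <- simulate_cohort(9, 3, months = c(2, 4, 6, 7:13), rng_seed = 20260930)
repeated_measures_anova(tab)
#> <kinetics_result> repeated-measures mixed ANOVA
#>   time:        F(9,90) = 16.418, p = 1.276e-15
#>   group:       F(1,10) = 875.140, p = 4.551e-11
#>   interaction: F(9,90) = 13.256, p = 2.958e-13
fit_linear_kinetics(tab)
#> <regression_fit> volume = 0.3131 -0.0096 x (month - 1) mL; R = 0.846 (n = 90)
cumulative_dose(13)
#> [1] 2626
```

The fitted slope and intercept recover the generating coefficients
(−0.01 mL/month, 0.315 mL) to within the per-cohort noise; the F tests
separate the declining transgenic arm from the plateaued wildtype arm.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end at desk
scale and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # cohort CSV + phantom scan series (NIfTI)
Rscript analysis/02_segment.R     # triplicate segmentation vs ground truth
Rscript analysis/03_kinetics.R    # ANOVA, late-window contrast, linear fit
Rscript analysis/04_dosimetry.R   # cumulative dose summary
```

`run_pipeline(run_config(...))` performs the same stages
programmatically from a serialisable YAML configuration.

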