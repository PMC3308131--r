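---
title: "Aerated-lung volumetry as a tumour-burden surrogate: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aerated-lung volumetry as a tumour-burden surrogate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerolung)
```

## The measurement problem

Transgenic mouse models of disseminated lung adenocarcinoma (such as
SPC-raf mice, where c-Raf overexpression under the surfactant protein C
promoter drives multifocal alveolar tumours) do not produce one
delineable nodule. Disease is diffuse and multifocal: by late stages
most of the lung is consolidated tumour. Direct tumour segmentation in
micro-CT is therefore impractical, but the *aerated* lung — parenchyma
that still contains air and images at strongly negative Hounsfield
units — segments readily. As tumour replaces aerated tissue, the
aerated volume declines; that decline is the burden surrogate this
package quantifies across monthly respiratory-gated micro-CT follow-up.

The package provides every stage of that workflow on synthetic data
with exact ground truth: a thorax phantom generator, seeded region
growing with overspill handling and triplicate averaging, calibrated
volumetry, longitudinal statistics, and radiation-dose bookkeeping.

## Region-growing semantics

`region_grow()` implements seeded 3D region growing with a
**percent-of-range tolerance**. Given seed voxels with mean HU $r$, a
tolerance fraction $t$ (default $0.02$) and the volume's full HU range
$R = \max - \min$, the acceptance window is

$$W = [\, r - tR,\ r + tR \,],$$

and the mask is the set of voxels connected to any seed (6-face
connectivity by default; 26 available) through voxels with HU in $W$.
Three choices deserve comment, because a "2% threshold tolerance" alone
does not pin down an algorithm:

* **Reference fixed at growth start.** $r$ is the pooled mean over the
  seed voxels and never updates during growth. Adaptive references make
  the result depend on visit order; a fixed pooled reference makes the
  mask a pure function of (volume, seeds, $t$, connectivity).
* **One shared window for all seeds.** All seeds grow a single flood
  with one window, rather than per-seed windows. A consequence worth
  knowing: a single outlier seed (say, dropped into the trachea at
  $-1000$ HU among 19 parenchyma seeds near $-650$ HU) falls *outside*
  the pooled window. It cannot grow, and is reported with the
  `seed_outside_window` diagnostic code rather than silently kept. The
  guarantee "every seed voxel is in the mask" therefore holds for
  in-window seeds; out-of-window seeds are surfaced, never grown.
* **Percent of image range, not of seed value.** $tR$ is a width in HU
  that adapts to the volume's contrast. An absolute-HU window can be
  had by choosing `tolerance_fraction` against a known range.

Seeds above $-300$ HU (clearly non-aerated tissue) additionally raise
`seed_in_dense_tissue`.

### Overspill and repositioning

A grown region that escapes the lung — through the open airway into the
air surrounding the animal — is *overspill*. `detect_overspill()` flags
it by two criteria: the mask touches a face of the grid boundary
(anatomy never does), or the mask exceeds 60% of the grid. Overspill is
detected, never silently repaired. `reposition_seeds()` is the explicit
repair step: it identifies the seeds whose own grown component reaches
the boundary and resamples exactly those from the aerated HU window
(default $[-900, -300]$), preserving the seed count. If only the size
criterion fired, there is no offending seed to move — the tolerance is
misconfigured — and the function refuses with an explanatory error.

### Triplicate protocol

`triplicate_volume()` mirrors the manual protocol this package
automates: three independent seedings (distinct RNG streams) of 20–40
seeds each, three segmentations, volumes averaged. On noise-free
phantoms all three replicates grow identical masks whenever the aerated
lung is one connected component per side; replicate scatter on real or
noisy data is what the averaging damps.

### Denoising before growth

White Gaussian HU noise interacts badly with a narrow acceptance
window: at noise SD 40 HU and a window half-width of $\sim 38$ HU, each
lung voxel falls inside the window with probability only $\sim 0.65$,
and the connected in-window subset of lung cannot exceed that fraction
— no seeding or connectivity choice recovers the lost volume. The noisy
protocol therefore applies an **iterated 3×3×3 median filter**
(`prefilter = "median"`, default 3 passes) before growing. The median
filter is edge-preserving (a flat interface voxel keeps its side's
value because its own population holds the majority of the
neighbourhood), and iterating it drives the image toward its median
root signal, stabilising interface voxels that a single pass leaves
flickering. Measured on default phantoms at noise SD 40, triplicate
recovery error is 1–4% of truth; noise-free runs skip the filter and
recover within 0.1%.

## The thorax phantom

`make_thorax_phantom()` builds a parametric-analytic thorax: a
soft-tissue body ellipsoid, two lung ellipsoids, a spine and sternum in
bone, a trachea-like airway tube connecting the left lung to the air
above the animal, and spherical tumour nodules replacing aerated lung.
Geometry is deliberately analytic rather than atlas-based: ground truth
is exact (the label grid is recorded before noise) and generation takes
well under a second, so every downstream stage is testable without any
animal data.

Compartment HU means default to background/airway air $-1000$, lung
$-650$, soft tissue $+40$, tumour $+30$, bone $+700$. These are
plausible values for murine micro-CT, not measurements; the model
species' tumour HU has not been published, and all that the method
requires is that tumour and soft tissue sit far above any aerated
acceptance window (the constructor enforces a $-300$ HU margin).

Two generator choices matter for interpretation:

* **Nodules coalesce.** Non-overlapping random sphere packing jams near
  38% volume fraction, while late disease reaches 60–70% burden — so
  nodule centres are drawn from remaining lung voxels and spheres may
  merge, as confluent tumour does. The requested burden is matched to
  within one voxel by truncating the last nodule to its voxels nearest
  the centre.
* **Noise is white and additive**, applied after optional Gaussian
  smoothing of the label-mean image, and clipped to $[-1024, 3071]$.
  Real reconstructed CT noise is spatially correlated and
  object-dependent; white noise at SD 40 HU is *harsher* than a real
  reconstruction at matched SD (no correlation for the median filter to
  exploit), which is the conservative direction for recovery claims.

The default grid is $96^3$ at 0.2 mm spacing — a desk-scale choice that
keeps a full phantom + triplicate segmentation under a second.
Reproducing the acquisition geometry this emulates (0.094 mm voxels,
32.8 mm field of view) is a configuration choice
(`phantom_spec(grid_shape = c(349, 349, 349), spacing_mm = 0.094)`),
not a code change. At the default scale the phantom is a shrunken
thorax: nodule radii (0.3–0.8 mm) are realistic in absolute terms and
therefore relatively coarse against the reduced lung.

What the phantom does **not** emulate: respiratory motion and gating
artefacts, scatter and beam hardening, reconstruction physics, airway
trees beyond one trachea, lobe structure, vessels. Passing recovery
tests on phantoms therefore demonstrates the correctness of the
segmentation and volumetry machinery under known geometry and noise —
not performance on real scans, which the original manual workflow
established separately.

## Longitudinal simulation

`simulate_cohort()` draws per-animal trajectories at requested months.
The transgenic mean in `eq1_pure` mode is the linear decline

$$V(\text{month}) = 0.315 - 0.01 \times (\text{month} - 1)\ \text{mL},$$

with i.i.d. Gaussian volume noise (default SD 0.02 mL). Wildtype
animals rise through normal growth (months 2–4, to a plateau of
0.36 mL) and then stay flat; the `piecewise_realistic` transgenic mode
rises with them before declining, reflecting that early volume gain is
normal growth, not disease. The plateau value and noise SD are the
package's own realism choices (an adult mouse aerated-lung volume and a
repeatability consistent with triplicate averaging); the decline's
slope and intercept are the generating coefficients that the
parameter-recovery analysis must return. `eq1_pure` is used for all
recovery and calibration work precisely because the target model is
then exactly true.

## Statistics

`repeated_measures_anova()` computes the two-way split-plot
decomposition from explicit sums of squares: between-subject SS split
into group and subject-within-group, within-subject SS into time,
time×group and residual, with $F_{\text{group}} =
MS_{\text{group}}/MS_{\text{subject(group)}}$ and the within-subject
effects tested against the within-subject residual. With every retained
animal measured at every requested month the cell frequencies are
proportional and the decomposition is orthogonal even with 9 vs 3
animals; the test suite verifies term-by-term agreement with
`aov(. ~ group * month + Error(animal/month))`. Missing follow-up is
handled by complete-case exclusion over the requested time points (no
imputation), with the excluded animals named in the result — mirroring
a study design in which one animal with curtailed follow-up is dropped
from the repeated-measures analysis.

Degenerate inputs are defined, not special-cased downstream: a constant
response gives $F = 0$, $p = 1$ for every effect (the 0/0 ratio is
resolved in favour of "no evidence"). No sphericity correction is
applied by default; Greenhouse–Geisser is available
(`sphericity_correction = "greenhouse-geisser"`), rescaling the
within-subject degrees of freedom by the $\varepsilon$ of the pooled
within-group covariance.

`fit_linear_kinetics()` is ordinary least squares of volume on
$(\text{month}-1)$, fit to the transgenic arm by default (a pooled-arm
fit is a flag); the correlation coefficient is reported unsigned, as is
conventional when the slope's sign already carries the direction.

Calibration properties, not printed historical values, are the
package's statistical claims: over 200 null simulations the group
test's type-I error sits in $[2\%, 10\%]$ at $\alpha = 0.05$, and over
200 alternative simulations (declining transgenic vs plateaued
wildtype, months 8–13) power exceeds 90%. The analogous recovery claim
for the growth model — mean fitted slope within $\pm 0.003$ of
$-0.01$ mL/month and mean intercept within $\pm 0.02$ of 0.315 mL over
200 cohorts — is what `scripts/acceptance.R` recomputes.

## Dose bookkeeping

`cumulative_dose()` and `cohort_dose_summary()` are deliberately plain
arithmetic over a `dose_model()` of protocol constants: 202 mGy per
scan (the 154 mGy CT protocol plus fluoroscopic scan planning at
19 mGy/min) multiplied by exam counts, summarised per cohort. The
197 mGy expected-mean constant is exposed alongside; cumulative figures
use 202, matching how such protocols report accumulated exposure. The
constants are taken as given — the package does not model dose from
scan physics.

## Known limitations

* At late-stage burden (≳ 0.5) the residual aerated lung fragments
  into pockets isolated by confluent tumour; region growing recovers
  only the seeded connected portion, so absolute volumes are biased low
  exactly when disease is worst. Longitudinal designs read the
  *relative* decline per animal, which is robust to this; the
  `burden_from_cohort()` per-animal-maximum reference follows that
  convention.
* The burden surrogate needs a reference volume. The per-animal maximum
  is a convention (configurable to a fixed cohort reference), not a
  measured healthy baseline.
* Median prefiltering erodes structures thinner than ~2 voxels; at the
  default spacing the airway tube survives, but very fine real airways
  would not.
* The ANOVA requires a balanced complete-case design after filtering;
  heavily unbalanced missingness calls for mixed-effects likelihood
  modelling, which is out of scope here.

## Problem sizes used by the test suite

Unit and property tests run on toy grids (≤ 32³) where brute-force
flood-fill and `aov` oracles are exact; recovery tests use the default
96³ phantom; statistical calibration uses 200 simulated cohorts of 12
animals × 10–12 months. The full suite completes in well under a
minute on one core — these sizes are the package's chosen desk-scale
study conditions, with scanner-scale geometry available through
configuration as noted above.
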