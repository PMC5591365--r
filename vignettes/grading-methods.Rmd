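---
title: "Methods: MRI complexity grading of glioblastoma and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRI complexity grading of glioblastoma and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmgrade)
```

## The grading model

Supratentorial glioblastoma lesions are described by five binary features
read from a pre-operative contrast-enhanced T1-weighted MRI, each worth
one point: periventricular or deep location (enhancing tumour strictly
within 10 mm of the ventricles), corpus callosum or bilateral location
(enhancing tumour extends into the callosum or crosses the midsagittal
plane), eloquent location (motor/sensory cortex, language cortex, insula,
or basal ganglia), large size (maximal diameter ≥ 40 mm), and associated
oedema (oedema reaching ≥ 10 mm beyond the enhancing margin). The score is
the unweighted sum; 0–1 is low, 2–3 moderate, and 4–5 high complexity.
Equal weighting and three classes keep the system simple and preserve
statistical power in small series.

The boundary semantics are deliberately asymmetric and are pinned by
tests: a ventricle distance of exactly 10 mm does *not* score the
periventricular point (strict `<`), while a diameter of exactly 40 mm and
an oedema extension of exactly 10 mm *do* score theirs (inclusive `>=`).
Thresholds are configurable through `grade_thresholds()`, but the defaults
are the published values and non-default values should be reported
alongside any results. Records with a missing measurement are rejected as
ungradable rather than imputed.

## Geometric measurements

All measurements operate on co-registered binary voxel masks
(`mask_volume`) with anisotropic spacing under an axis-aligned RAS frame;
voxel `(1,1,1)`'s centre sits at the stored origin. Distances are
voxel-centre to voxel-centre:

* `min_surface_distance()` and `oedema_extension()` use an exact
  Euclidean distance transform (separable lower-envelope algorithm,
  spacing-aware) over the grid, then take the minimum over tumour voxels
  or the maximum over oedema voxels. Sub-voxel surface offsets are not
  modelled, so each length carries an error of at most one voxel diagonal
  relative to continuous geometry — about 1.7 mm at 1 mm isotropic
  resolution, comparable to the precision of clinical reading.
* `feret_diameter()` is the exact maximal pairwise voxel-centre distance,
  searched over boundary voxels (which contain the extreme points of the
  set). The default is the well-defined 3D diameter; an axial slice-wise
  mode is offered because radiologists often measure in-plane, and it is
  not recorded which convention the original readers used.
* `involvement()` calls a region involved at ≥ 1 overlapping voxel by
  default ("extends into" has no published minimum); the threshold is
  configurable.
* `crosses_midline()` requires voxel centres strictly on both sides of
  the plane; centres exactly on it count for neither. The midline
  defaults to the scanner `x = 0` plane because the original study never
  states how bilaterality was operationalised; an explicit plane can be
  supplied.
* Multifocal enhancing disease is treated as one point set (union), the
  conservative reading of "contrast-enhancing tumour".

"Deep location" is collapsed onto the 10 mm ventricle-distance rule, as
in the published score table; no separate deep-white-matter region is
modelled.

## Synthetic phantoms

`make_phantom()` rasterises an ellipsoidal tumour, an oedema shell of
commanded thickness (all voxels within that distance of the tumour set),
a ventricle slab at a commanded gap, optional boxes overlapping the
tumour for the callosal and eloquent regions, and a commanded laterality.
Two lattice-alignment choices make the ground truth analytic rather than
discretisation-limited: semi-axes are snapped to whole voxels (with an
inclusive surface test, so the pole voxels realise the full `2·max
semi-axis` diameter exactly), and the slab's near face is aligned to the
rasterised tumour's extreme voxel plane a whole number of voxels away, so
the minimum centre-to-centre distance equals the commanded gap exactly.
The commanded oedema thickness is attained along the pole line of the
x-axis, giving recovery within one voxel spacing. The randomised suite
(`random_phantom_spec()`) draws semi-axes of 4–18 mm, oedema 0–15 mm and
gaps −3–15 mm at 1 mm isotropic spacing — dimensions typical of the
tumours the grading system targets.

Phantoms exercise the geometry, not the imaging: they contain no
intensity information, no segmentation uncertainty, no registration
error, and their shapes are convex. Passing phantom recovery therefore
demonstrates correctness of the geometric pipeline given masks, not
robustness to real segmentation variability.

## Simulated cohorts

`simulate_cohort()` draws the five flags per patient as independent
Bernoulli variables with the validation cohort's prevalences (68/88,
29/88, 38/88, 62/88, 61/88) by default — only the marginals were
published, so independence is the neutral choice; a Gaussian-copula
latent-correlation matrix is available to study dependence. Score and
class follow from the grading rules; complete resection and major
complication are drawn from the class-conditional rates of the published
outcome table (7/14, 7/45, 1/29 and 0/14, 1/45, 2/29). A major
complication receives a Clavien-Dindo value uniform on {3b, 4a, 4b, 5}
and others uniform on {none, 1, 2, 3a}, since only the above-3a dichotomy
enters any analysis. One seeded generator drives each call; the seed is
recorded on the output.

The second rater is simulated at the *feature* level: each flag flips
independently with probability ε, and the rater's score and class are
recomputed. Raters plausibly disagree on reading features rather than on
arithmetic, and feature-level noise makes class-level agreement a
monotone one-parameter family, so `calibrate_rater_noise()` can bisect ε
to hit a target κ. The published inter-rater agreement (κ = 0.625, SE
0.066) cannot be re-derived — the rater cross-table was not printed — so
the package demonstrates the calibration (an ε near 0.09 reproduces
κ ≈ 0.625 at n = 10\,000), not a reproduction of that number. Whether the
published κ was computed on 3 classes or 6 score levels is likewise not
stated; the package defaults to the 3-level classes and exposes the
score scale as an option.

## Validation statistics

`pearson_chi2()` is the plain Pearson statistic without continuity
correction, which is what reproduces the published resection p-value
(χ² = 14.615, df = 2, p = 0.00067, printed as 0.0007) from the
grade-by-resection counts. The complications table recomputes to
p = 0.4152 against a printed 0.4148; the residual is consistent with an
intermediate rounding in the original analysis. Expected counts below 5
(below 1, for the complications table) set a warning flag but do not
block the test, mirroring the original analysis; the flag documents the
caveat. All-zero rows or columns are dropped with a warning first.

`cohens_kappa()` reports κ = (p_o − p_e)/(1 − p_e) with, by default, the
large-sample asymptotic standard error of Fleiss, Cohen and Everitt —
the estimator major statistics packages print — and optionally the
simpler `sqrt(p_o(1−p_o)/(n(1−p_e)^2))`. κ is reported as undefined when
the margins put all mass in one category. Table percentages round
half-up to one decimal, matching how the published tables print (base
R's half-even rounding would turn 33.0% into 32.9% in edge cases).

## Problem sizes and numerical choices

The shipped analyses run at desk scale: 55 random phantoms on grids of
roughly 50–80 voxels per axis, simulation checks at n = 10\,000–100\,000
patients, a 10\,000-replicate bootstrap for the κ standard error, and a
20\,000-draw permutation check of the chi-square p — sizes chosen so
binomial/Monte-Carlo error is well below the effects being checked while
the whole suite runs in well under a half hour on one CPU. Distance
transforms are exact (no approximation parameter); ellipsoid
rasterisation uses an inclusive surface test with a 1e-9 relative
tolerance against floating-point boundary misses.

## Known limitations

* Masks are inputs: no intensity-based segmentation, registration,
  or DICOM handling.
* Only the axis-aligned RAS frame is supported for the index-to-mm
  mapping; oblique acquisitions must be resampled upstream.
* The simulated cohort matches published marginals, not any true joint
  feature distribution; dependence choices are explicitly synthetic.
* Survival endpoints are out of scope; the validation covers extent of
  resection and complications only.
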