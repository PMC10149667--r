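---
title: "Bone-centered 3D femoral angle measurement: model, validation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone-centered 3D femoral angle measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femur3d)
library(dplyr)
```

## The measurement problem

Femoral torsion (anteversion), neck inclination and varus angles guide the
surgical correction of limb deformities, but their values depend strongly on
the measurement technique. Radiographic projections conflate torsion and
inclination with positioning; visually guided 3D renderings depend on the
chosen view. The approach implemented here removes the positioning problem
entirely: a *bone-centered* coordinate system is constructed from anatomical
landmark coordinates, and all angles are computed from vector geometry in
that frame, so the result is invariant to how the bone was positioned in the
scanner gantry.

`femur3d` implements the full chain — landmark containers, the femoral-head
sphere fit, frame construction, the six angle variants — plus the two
validation instruments such a technique needs: a parametric
torsional-deformity phantom (accuracy) and a simulated clinical cohort with
observer structure (precision), together with the method-comparison
statistics used to judge them (Bland–Altman, Passing–Bablok, Bland's CV for
repeated measurements).

## The bone-centered frame and the six angles

From the nine landmarks (`FHC`, `FNC`, `FNBC`, `LCC`, `MCC`, `PS1`, `PS2`,
`DS1`, `DS2`; see `?LANDMARK_NAMES`) the frame is built as:

* $\hat L$ — the longitudinal axis, pointing proximally. Three variants: the
  proximal two-point axis (*pd*), the distal two-point axis (*dd*), and the
  total least-squares line through all four shaft centers (*td*, the
  default). The plane normal to $\hat L$ is the transverse plane.
* $\hat M$ — the retrocondylar axis `LCC → MCC` (lateral to medial)
  orthogonalized against $\hat L$.
* $\hat C = s\,(\hat L \times \hat M)$ — the craniocaudal axis, with the side
  sign $s$ (+1 left, −1 right) chosen so $\hat C$ points cranially for both
  sides. The frame is therefore right-handed for left femora and left-handed
  for right femora; this is exactly what makes the *signed* torsion
  convention (antetorsion positive) hold on both sides without any
  special-casing downstream.

The angles:

* **FTA** (torsion): signed angle from the retrocondylar axis to the neck
  axis, both projected into the transverse plane; the rotation sense is
  taken about $s\hat L$ so cranial deviation of the neck is positive.
  The neck axis runs from `FNC` (variant *NC*) or `FNBC` (variant *NBC*) to
  the head center.
* **FIA** (neck inclination): the direct, unprojected 3D angle between the
  neck axis and the distally pointing longitudinal axis.
* **FVA** (varus): the *pd* or *td* axis and the distally pointing *dd* axis
  projected into the dorsal plane (normal $\hat C$); reported as the raw
  near-180° angle, matching the clinical reporting scale, with an auxiliary
  signed deviation `180° − angle` (medial deviation of the distal segment =
  varus = positive) in `fva_*_dev`.

Every result row carries `torsion_axis` / `fia_axis` technique tags, because
values from different axis definitions are not interchangeable.

The head center itself comes from `fit_sphere()`: an algebraic linear
least-squares sphere (the linearization of $|p-c|^2 = r^2$) followed by
geometric Gauss–Newton refinement of the center with the radius profiled out
as the mean center-to-point distance. The algebraic stage gives a
closed-form, basin-safe start; the geometric stage minimizes the orthogonal
residuals that are actually meaningful for a partial, noisy cap. The RMS
orthogonal residual is reported so callers can gate fit quality.

## What the phantom emulates

`phantom_spec()` + `build_canonical_landmarks()` generate an idealized femur
whose ground truth is known *exactly*: shaft centers on the canonical long
axis, condyle centers symmetric about it with a caudal offset, and the head
placed so the constructed landmarks return exactly the nominal inclination
(default 135°) and antetorsion (default 21.5°, the physiological baseline
that corresponds to the hinge's 0° setting). `apply_hinge()` rotates all
landmarks proximal to the hinge level (default mid-diaphyseal) about the
long axis, so the true torsion is *exactly* `21.5° + hinge` — the shaft
landmarks lie on the rotation axis, which is why the closure test can demand
1e-9° rather than a statistical tolerance. `apply_pose()` adds an arbitrary
rigid pose; `perturb_observer()` adds isotropic Gaussian landmark noise;
`simulate_goniometer()` models the 1°-increment reference instrument with an
alignment bias and reading noise, rounding half-away-from-zero (a symmetric
physical scale is read outward from zero; the convention matters only for
readings ending in exactly 0.5°, and it is documented rather than claimed
from evidence).

`run_accuracy_experiment()` chains these per preset and compares the paired
(goniometer, software) torsion values with both agreement statistics. With
all noise at zero the measured column reproduces the preset column exactly;
with an injected goniometer alignment bias of −2.1° the Bland–Altman bias
recovers +2.1° on average — the mechanism proposed for the systematic offset
observed in the physical phantom study this design mirrors.

Deliberate idealizations: the phantom is a landmark-level object (no CT
volume, no DICOM, no partial-volume or segmentation effects); observer noise
is isotropic and homoscedastic across landmarks, whereas real placement
error is anisotropic (worst along the slice direction) and
landmark-dependent; the goniometer bias is a single constant. Passing tests
therefore validate the *geometry and statistics chain*, not image-domain
effects.

## What the cohort generator emulates

`cohort_spec()` + `simulate_cohort()` model a bilateral clinical cohort
(default 34 dogs, both sides) measured by two observers, observer 1 twice
(intraobserver pairing: O1 session 1 vs session 2; interobserver pairing:
O1 session 1 vs O2 — the pairing is configurable since study designs vary).
Per dog and side the true torsion, inclination and dorsal-plane shaft bend
are drawn from Gaussians. Defaults were chosen once, from the magnitudes
published for clinical canine femora: torsion mean 23° and inclination mean
137° with SD 3°, bend mean 4.5° (so projected varus angles fall near 175°).
The `FNC` landmark is offset from the geometric neck chord (0.4 mm cranial,
4.6 mm proximal by default): a short back-of-envelope on the default
geometry (neck chord 25 mm at 137° inclination) shows these offsets
reproduce the systematic clinical observations that NC-based torsion reads a
few degrees lower than NBC-based torsion, and NC-based inclination roughly
20° lower than NBC-based — both consequences of the real neck center not
lying on the FNBC–FHC chord.

Observer landmark noise defaults to SD 0.12 mm (observer 1) and 0.20 mm
(observer 2) per coordinate: sub-voxel repeatability for manual point
placement on 0.6 mm CT data. Under these values the simulated cohort
reproduces the published repeatability *structure*: torsion CVs of a few
percent (NC worse than NBC, interobserver worse than intraobserver), and
inclination and varus CVs well below torsion's — the larger absolute angles
and, for inclination, the absence of a projection step make them relatively
more precise.

Two things the cohort generator does **not** claim: the published clinical
CVs themselves are not desk-reproducible (they depend on the real dogs' CT
data and the real observers), so precision is validated by *parameter
recovery* instead — the generator can inject an explicit within-subject CV
(`within_subject_cv_pct`, multiplicative Gaussian measurement noise so the
within-subject SD is proportional to the subject mean, which is exactly the
quantity Bland's RMS estimator targets), and the estimator must recover it
(±0.5 % absolute at 500 subjects). And it does not model real anatomical
shape variation beyond the three drawn parameters.

## Statistics

* `bland_altman()`: bias `mean(y − x)`, sample SD (n−1), limits of agreement
  at ±1.96 SD (fixed multiplier, α = 0.05 throughout).
* `passing_bablok()`: all pairwise slopes with `x_i ≠ x_j` skipped (not
  errored) and slopes exactly −1 excluded; the estimate is the shifted
  median with offset K = #{slopes < −1}; intercept `median(y − slope·x)`;
  slope CI by the rank-based normal approximation
  `C = z₀.₉₇₅ √(n(n−1)(2n+5)/18)`. Ties are handled by the standard
  sorted-order median. The cusum linearity test and bootstrap CIs are out of
  scope.
* `cv_repeated()`: Bland's duplicate-measurement CV,
  `100·√(mean(s_i²/m_i²))` (RMS method, default) — for k = 2 this reduces to
  `s_i² = d_i²/2` — with the log-method (`100·(exp(s_w) − 1)` from the
  within-subject variance of log values) available as a sensitivity flag,
  since published workflows do not always state which variant was used. CV
  is refused when any subject mean is ≤ 0 (undefined near zero).
* `rate_cv()`: excellent < 3 %, good < 10 %, moderate/fair < 15 %, poor
  otherwise; boundaries belong to the worse class.

The precision summary reports, per angle and side: the grand mean, the
within-subject SD `√(mean(s_i²))` (this, not the between-subject SD, is what
a repeatability table's SD column tracks — it equals mean × CV/100 when the
CV is small), the CV, and its rating.

## Numerical choices and degenerate inputs

* Angles are kept at full double precision internally; rounding (0.1° or
  0.01°) happens only at report time (`diff_of_means()` rounds to 2 dp, the
  packaged fixtures store the printed 0.1° precision).
* Axis orientation is fixed by rule (proximally pointing, via the PS-vs-DS
  centroid difference), so swapped landmark input order cannot flip a sign.
* Degenerate inputs error loudly and specifically: fewer than 4 sphere
  points or a rank-deficient design (coplanar points), a retrocondylar axis
  parallel to the longitudinal axis, a neck axis parallel to the projection
  normal, non-orthonormal pose matrices, missing landmarks (named), CV with
  nonpositive subject means, fewer than 3 statistic pairs.
* Projection near-degeneracy is detected at 1e-9 relative norm; frame
  orthonormality holds to 1e-12 by construction.
* Reproducibility: every stochastic function takes a seed; compound drivers
  derive per-stage sub-streams deterministically from one top-level seed
  (`cohort_spec(seed = )`, `run_accuracy_experiment(seed = )`), so identical
  configurations replay identically while stages stay independent.

## Problem sizes used in the validation suite

The shipped tests run the sphere-fit consistency sweep at n ∈ {50, 500,
5000} points × 50 seeds, the oracle comparison of the shifted-median
regression on 200 random ≤ 8-point datasets, rigid-pose invariance over 100
random poses, CV parameter recovery on a 500-dog cohort, and the
bias-recovery experiment over 50 seeded runs of 13 presets — sizes at which
the Monte-Carlo error of each check is comfortably below its assertion
tolerance.

## Worked example

```{r phantom}
lm <- build_canonical_landmarks(phantom_spec(hinge_angle_deg = -30))
femoral_torsion(lm, "NBC")   # 21.5 - 30
measure_all(build_canonical_landmarks(phantom_spec()))
```

```{r stats}
pairs <- load_table1_fixture()
bland_altman(pairs, goniometer_deg, software_deg)
passing_bablok(pairs, goniometer_deg, software_deg)
```

```{r cohort}
res <- run_precision_experiment(cohort_spec(n_dogs = 10, seed = 1))
res$summary |> select(angle, side, mean_intra, cv_intra, rating_intra)
```

## Known limitations

* Landmarks are inputs; there is no automatic landmark detection and no
  image handling of any kind.
* Sagittal-plane (pro-/recurvatum) angles and translational deformity
  components are not measured — the angle set is deliberately the six
  technique-tagged variants above.
* Varus is reported from the dorsal-plane projection; a bend outside that
  plane is invisible to it by construction (and tested to be).
* The generators produce plausible, structured data for validating the
  measurement chain; they are not anatomical shape models, and agreement of
  simulated CVs with published clinical CVs is qualitative (ordering and
  magnitude range), not numeric.
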