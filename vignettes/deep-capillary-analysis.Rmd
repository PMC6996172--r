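---
title: "Methods: quantifying the deep capillary plexus from en-face OCT-A"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the deep capillary plexus from en-face OCT-A}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepangio)
```

`deepangio` analyses en-face OCT-angiography images of the retinal deep
capillary plexus (DCP) in diabetic eyes: artifact-aware quality
control, quantification into three morphology metrics, test–retest
reliability, and clustered regression of the metrics on clinical
factors. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic data can and cannot show.

## Image model and coordinate conventions

An `enface_angiogram` is a square grayscale matrix (default 320 × 320
pixels over 3.0 mm, so 9.375 µm per pixel) with vessels bright and
background dark — the standard en-face OCT-A convention, under which
capillary non-perfusion appears as dark areas. The mm coordinate frame
uses pixel centers with its origin at the image center, which is taken
to be the fovea; all physical thresholds (window sizes, annulus radii,
component areas) are expressed in mm or mm² so the rules are covariant
in geometry rather than tied to a pixel count.

## Quality control

The QC battery mimics the decision rules a masked reading-center
grader applies, but with numeric scores. Each detector returns a score
and a flag; `apply_qc()` takes the union of flags and assigns a single
`primary_reason` in the fixed priority order *projection > blur >
motion > signal_loss > low_quality > off_center > seg_error*. Whether
one artifact would have sufficed when several co-occur is genuinely
undecidable from a reason-count table, so the priority order is a
package decision, chosen to mirror the order in which exclusion
reasons are conventionally reported.

* **Projection** (`detect_projection_artifact`, threshold 0.25): a
  two-step rule. Step 1 extracts the SCP large-vessel mask
  (binarization, morphological opening at a 0.04 mm caliber threshold,
  removal of components under 0.02 mm²) and measures the co-elevation
  of DCP intensity under that mask against the off-mask background,
  scaled so that a 0.15 contrast (on the 0–1 scale) saturates the
  term. Step 2 measures how much of the mask the binarized DCP image
  covers: a true projection is a *continuous* vessel shadowing the
  whole SCP course, whereas genuine DCP texture under the mask is a
  series of vortex units covering only part of it. The score is the
  product of the two terms, so both co-localization and continuous
  morphology are required.
* **Blur** (`detect_blur`, threshold 0.35, flag when *below*): the
  fraction of image energy left after removing a σ = 2 px Gaussian
  low-pass, normalized by image contrast. A constant image scores 0.
* **Motion** (`detect_motion_artifact`, threshold 0.5): the minimum
  correlation between adjacent rows, rescaled so that a correlation at
  or below 0 saturates the score (on intact texture adjacent rows
  correlate at about 0.7; a lateral row-block displacement collapses
  the correlation across the break), combined with detection of bright
  residual motion lines (rows whose mean intensity is a > 12-MAD
  outlier). Because only *relative* displacement counts, a uniform
  shift of the whole image scores zero, and near-zero rows are ignored
  so a blink band is not double-counted as motion.
* **Signal loss** (`detect_signal_loss`, threshold 0.08): the longest
  run of rows with mean intensity below 0.05, as a fraction of image
  height.
* **Centration** (`check_centration`, threshold 0.5 mm, strict
  inequality): distance from the detected FAZ centroid to the image
  center; an undetectable fovea is itself flagged.
* **Low quality**: the device-reported quality score, excluded when
  *strictly below 40* (40 itself passes). **Segmentation error** is an
  input metadata flag: B-scans are not carried by the en-face
  container, so boundary-tracing errors must be asserted upstream.

Detector thresholds are the package's numeric stand-ins for a human
reader's judgment. They were calibrated once on synthetic fixtures at
the default artifact magnitudes and are exposed as arguments; on a
60-image half-clean batch every detector reaches recall and
specificity of at least 0.9 (in practice 1.0 at the defaults, since
the synthetic artifact magnitudes are far from threshold).

## Quantification

`quantify_dcp()` runs denoise → binarize → {FAZ, VD, skeleton → FD}.

* **Denoising** is a bilateral filter (window radius 1 px, range sigma
  45 intensity levels): spatial Gaussian weights attenuated across
  intensity edges, so capillary boundaries survive while noise in
  locally uniform areas is averaged. A median filter was rejected
  because at this texture scale (capillary caliber ~1–2 px) it erodes
  thin ridges faster than it removes noise, *increasing* the error to
  the clean image. Strength 0 is the identity.
* **Binarization** is locally adaptive mean thresholding with a window
  of 0.25 mm and an offset of 0.03 (0–1 scale): a pixel is vessel when
  it exceeds its local mean by the offset. This makes the rule
  invariant to uniform intensity offsets and robust to slow
  illumination gradients; a constant image yields an empty mask. The
  method is a package decision — adaptive mean thresholding is the
  conventional choice for en-face OCT-A — with both parameters
  exposed.
* **FAZ area** is the connected non-vessel component containing the
  image center (or, when the center pixel falls on a vessel or in a
  capillary-scale gap, the nearest dark component of at least 0.02 mm²
  within a 0.5 mm search disc), after morphological closing of the
  vessel mask at capillary scale (0.03 mm). The closing-then-component
  rule (rather than an explicit contour) is a package decision; the
  area is *exactly* the pixel count times the pixel area, with no
  boundary smoothing.
* **Vessel density** is the percentage of the parafoveal annulus
  (outer radius 1.5 mm, inner 0.5 mm, both inclusive) not covered by
  non-perfusion, where a non-perfusion region is a dark connected
  component whose **total** area strictly exceeds 0.02 mm² — the
  comparison is done in mm² to avoid pixel-rounding dialects, and a
  component straddling the annulus is classified by its total area but
  only its intersection with the annulus is subtracted. The central
  avascular zone normally lies inside the 0.5 mm inner disc and so
  does not contribute; if it crosses the inner rim its overlap *is*
  counted, since the definition provides no exemption. Dark components
  use 4-connectivity (the standard dual of 8-connected foreground).
* **Skeletonization** is Zhang–Suen parallel thinning, with a
  safeguard restoring one pixel for any component the parallel scheme
  annihilates outright (a known failure for 2 × 2 blobs), so the
  component count is preserved exactly.
* **Fractal dimension** counts occupied boxes over the dyadic ladder
  s = 2, 4, …, n/4 on the full image grid and reports the negative
  least-squares slope of log N(s) against log s. The ladder top of n/4
  keeps at least 16 boxes at the coarsest scale; on the 320-grid the
  analytic limits are met essentially exactly (line → 1.000, plane →
  2.000, Sierpinski triangle → 1.58496).

No axial-length magnification correction is applied to any metric:
image-size correction methods have been validated for the superficial
plexus only, so the per-eye axial length is instead carried as a
covariate into the association models.

## Reliability

`compute_icc()` implements the two-way random-effects,
absolute-agreement, single-measure ICC(2,1) from the two-way ANOVA mean
squares, with the McGraw–Wong F-based confidence interval. ICC(2,1) is
the standard choice for test–retest of a single device reading; since
published reports sometimes quote average-measure values, ICC(2,k) is
available via `measure = "average"` and the `model_label` field records
which was computed. Duplicated scans give exactly 1; identical values
throughout raise a degenerate-variance error rather than 0/0; fewer
than 5 complete pairs is treated as insufficient data.

## Association workflow

`run_full_analysis()` reproduces the clustered univariate →
multivariable workflow: continuous predictors are standardized to mean
0, SD 1 *on the analysis rows of each cohort variant separately* (so
per-SD effects always refer to the analyzed sample), DR severity
enters as three dummies against "no DR", and every candidate factor is
screened univariately at two-sided p < 0.05 (the conventional
threshold; exposed as `alpha`), with the DR block selected when any
dummy is significant. Selected factors enter one multivariable model
per outcome. The whole procedure is then repeated on the subset
without macular edema, because edema fluid can masquerade as
non-perfusion and inflate the apparent dropout.

The estimator is a linear GEE: identity link, exchangeable working
correlation across the one or two eyes of a subject (the natural
structure for fellow eyes), moment estimators for the dispersion and
the working correlation, and cluster-robust sandwich covariance. With
one eye per subject or a zero working correlation the point estimates
reduce to OLS (verified to 1e-6 in the tests, with the sandwich SEs
cross-checked against `sandwich::vcovCL`). Missing covariate values are
handled complete-case per model; a rank-deficient design raises an
error naming the aliased terms rather than silently dropping them.

## What the synthetic data emulate — and what they do not

The DCP generator renders the morphology that distinguishes the deep
plexus: polygonal (Voronoi-like) capillary units whose capillaries
radially converge on a vortex epicenter (default 25 units/mm², i.e. a
0.2 mm cell pitch), closed capillary loops along cell boundaries so
that inter-capillary gaps stay below the 0.02 mm² non-perfusion
cutoff, a circular avascular zone of known radius bounded by a
perifoveal capillary ring, optional dark dropout discs, and additive
Gaussian noise (SD 8 of 255). The SCP generator renders a finer
polygonal mesh plus smoothly curving large radial vessels of known
caliber in disjoint angular sectors, whose mask drives projection
injection and detection. Artifact injectors append, never remove,
ground-truth labels, and magnitude 0 is always the identity.

Cohorts draw covariates from Gaussian marginals with configurable
means/SDs (defaults chosen as typical of a diabetic clinic population:
age 60.7 ± 13.2 y, HbA1c 7.48 ± 1.33%, axial length 23.88 ± 1.34 mm,
and so on), DR severity with probabilities 0.428/0.254/0.227/0.091 and
DME at 0.144 per eye, and outcomes as linear functions of the
standardized predictors plus a subject-level random effect inducing an
inter-eye correlation of 0.4 by default. The default effect sizes are
the magnitudes a multivariable fellow-eye analysis of the DCP reports
(e.g. −0.891 on FD for severe-vs-no DR), so parameter-recovery runs
exercise realistic signal-to-noise. Marginals are not truncated, so a
small fraction of physiologically impossible values (e.g. a negative
diabetes duration) can occur; this is deliberate, because the
marginal-recovery checks compare sample means/SDs against the
configured targets.

Passing tests on these fixtures show that the measurement chain
recovers known geometry and injected effects; they cannot show
robustness to everything real DCP images contain — speckle that is not
additive-Gaussian, segmentation-error shadows, pathology-driven
texture (microaneurysms, cysts), or device-specific banding. The
quality-score metric is likewise assigned, not computed, since device
scoring algorithms are proprietary.

## Problem sizes and numerical choices

The shipped tests use 320 × 320 images (single images to ~50-image
batches), cohorts of 80–800 subjects, 500-replicate coverage
simulations at 200 subjects, and 20-cohort recovery runs at 400
subjects — sizes chosen so each recovery estimate has a standard error
comfortably below the tolerance it is checked against. GEE iteration
stops when coefficients move less than 1e-10 (at most 50 iterations);
the working correlation estimate is clamped to [−0.9, 0.95]; the
box-counting fit requires at least two ladder points; ties in the FAZ
component search are broken toward the component nearest the center.

## Known limitations

* QC thresholds are calibrated on synthetic artifact magnitudes; real
  borderline artifacts will produce intermediate scores, and the
  thresholds should be re-calibrated against reader labels before any
  clinical use.
* The projection score needs a paired SCP image; without one the check
  is reported as not assessed and the eye is never auto-passed.
* FD from box counting depends mildly on the ladder range; the default
  ladder is reported alongside any cross-study comparison.
* The GEE assumes an identity link and homoscedastic residuals within
  the working model; robust SEs protect inference, not efficiency,
  under misspecification.
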