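---
title: "Registration and longitudinal analysis of RNFL thickness maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration and longitudinal analysis of RNFL thickness maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlongreg)
```

## The problem

Peripapillary retinal nerve fiber layer thickness (RNFLT), measured by OCT
ring scans around the optic nerve head (ONH), is a standard biomarker for
glaucoma progression. In longitudinal studies each imaging session places
the scan pattern slightly differently: the operator re-centers the ring by
eye, and the subject's globe orientation varies between sessions. The
resulting misalignment — a small translation, rotation, and optical
magnification change between sessions — moves anatomical structure across
the fixed sector boundaries used for reporting (the all-rings average, the
four TSNI quadrants, and the twelve 30° clock-hour sectors). Averaged over
a sector this is mostly extra noise; if the misalignment *drifts* over the
study it masquerades as longitudinal change in sectors that sit on steep
angular thickness gradients.

`octlongreg` implements the full chain needed to study and correct this:
two similarity-transform registration algorithms for the en-face fundus
images that accompany each session, a vessel-overlap metric for
registration quality, the 17 sector features, linear mixed-effects models
for the longitudinal analysis, and a synthetic-data generator with known
ground truth that stands in for the original primate data.

## Geometry and the transform model

All rasters are square grids with a physical pixel size; the canonical
working frame is 512 × 512 pixels covering a 3 × 3 mm field of view
(≈ 5.9 μm/px). Coordinates are 0-based and pixel-centered, `x` increases
along columns, `y` downward along rows. The misalignment model is a
similarity transform — scale about the image center, then rotation about
the center (positive counter-clockwise as displayed), then translation —
because the physical sources are ring placement (translation), globe
torsion (rotation), and axial-length/working-distance change
(magnification). Nothing in the data motivates shear or deformation, so
the model is deliberately linear.

Resampling is by inverse mapping with bilinear interpolation for intensity
and thickness images and nearest-neighbour for binary vessel masks (so
masks stay binary; thresholding a bilinearly warped mask would inflate
vessel width). Every raster carries a validity mask: pixels introduced by
warping are zero-filled *and flagged invalid*, and every downstream
computation — intensity histograms, correlations, overlap counts, sector
means — uses only valid pixels. For bilinear interpolation a pixel is
valid only if all four contributing source pixels are valid, which keeps
thickness values from being blended with out-of-annulus padding.

## Mutual-information registration

The automatic algorithm registers a target fundus image to the reference
by maximizing mutual information
\(MI(A,B) = H(A) + H(B) - H(A,B)\), with Shannon entropies computed from
equal-width intensity histograms (64 bins over the 8-bit range [0, 255];
the count is configurable, 64 being standard practice for 8-bit retinal
imagery). Logarithms are base 2; the argmax is invariant to the base.
Histograms are restricted to pixels valid in both images, so the criterion
compares content on the overlap region rather than rewarding alignment
with zero padding.

The search is exhaustive, in two stages:

* **Coarse:** a joint grid over translation ±25 px in steps of 5 and
  rotation ±10° in steps of 2°, scale fixed at 1 (11 × 11 × 11 = 1331
  evaluations). Searching the three parameters simultaneously avoids the
  local maxima that one-parameter-at-a-time search stalls in at this
  stage.
* **Fine:** five sequential 1-D searches — scale ×(0.85…1.15) step 0.01,
  x-translation ±20 px step 1, y-translation likewise, rotation ±20° step
  0.1°, and scale again — each centered on the current estimate. The fine
  grids are interpreted as *relative* windows around the running estimate;
  this is what makes a ±20° fine rotation window consistent with a ±10°
  coarse range (it is a refinement corridor, not a second global search).

Two numerical choices matter. Every candidate is evaluated by resampling
the *original* target with the full candidate transform, never by
re-warping an already-warped image, so interpolation error does not
accumulate across stages; a consequence is that the fine objective is
non-decreasing stage over stage (each grid contains the current estimate).
Exact MI ties are broken toward the candidate closest to the identity
(lexicographically by |tx|+|ty|, |rotation|, |scale−1|), so degenerate
inputs resolve to "do nothing" rather than an arbitrary grid corner.

## Log-polar cross-correlation registration

The semi-automatic algorithm operates on segmented blood-vessel masks
(manual in the original workflow; synthetic or user-supplied here).
Resampling a mask onto (angle, log-radius) axes about an origin turns
rotation about that origin into a circular shift along the angle axis and
isotropic scaling into a shift along the log-radius axis. Cross-correlating
the target's log-polar image against the reference's then yields rotation
and scale from the peak's coordinates — but only if the origin is right,
because the log-polar map is not translation-invariant. The algorithm
therefore scans all candidate origins in a bounded window, and the
winning origin supplies the translation.

Correlations are computed with the FFT: circular along the periodic angle
axis, linear (zero-padded) along the log-radius axis. Inside the origin
scan the padding is bounded by a maximum scale-shift parameter (default 32
bins, covering scale factors far beyond the 0.85–1.15 window of interest)
rather than the full 2n−1, which keeps the per-origin FFT small; the
public `cross_correlate_logpolar()` defaults to full padding and is the
path verified against a brute-force spatial correlation in the tests. Raw
(unnormalized) correlation is the default, with per-origin normalized
correlation available as a flag.

The search runs at two resolutions: a coarse pass on masks block-averaged
to 1/4 size with origin candidates within ±10 subsampled pixels of the
center (so ±40 px of translation at full resolution, matching the global
translation bound), then — after applying the coarse correction to the
target — a fine pass at full resolution with origin candidates within ±4
px, re-estimating translation, rotation, and scale. Estimates are
bin-quantized (no sub-bin peak interpolation), in keeping with the grid
character of the whole method; a final correction whose translation
exceeds the 40 px bound raises an error naming the offending component,
and a coarse scan that peaks on the boundary of its origin window sets a
`boundary_hit` flag, so an out-of-bounds truth is never silently
mis-reported.

Log-polar sampling bounds: `r_min = 2` px avoids the log singularity;
`r_max` is fixed at the frame half-width minus one for *all* origins, with
samples beyond the frame edge contributing zeros. A per-origin `r_max`
(shrinking to the nearest edge) would change the log-radius bin width per
candidate and break the matched-geometry requirement of correlating every
candidate against one reference log-polar image. Bin counts are 180 × 128
at the coarse level and 360 × 384 at the fine level: one angle bin = 1° and
a log-radius bin width near 1% in scale, so bin quantization alone stays
inside a 0.01 scale tolerance.

## Registration quality: vessel precision and recall

Registration quality is scored on the vessel masks, inside the overlapped
scanning region of the pair (pixels valid in both rasters): true positives
are vessel pixels present in both masks, false positives target-only,
false negatives reference-only, giving
`precision = TP/(TP+FP)` and `recall = TP/(TP+FN)`. Matching is strictly
pixelwise — no skeletonization or tolerance bands — and transformed masks
are warped nearest-neighbour. An empty denominator (a mask with no vessel
pixels in the overlap) yields a flagged missing value rather than 0,
because the downstream comparison models treat the metrics as continuous
responses and a hard 0 would be a fabricated observation.

## The 17 RNFLT features

A thickness map is a 100-ring × 100-a-scan polar grid, ring radii equally
spaced from 0.75 to 1.5 mm. For feature computation the map is rasterized
onto the Cartesian annulus (nearest polar sample per pixel), which makes
the sector means implicitly area-weighted and lets the same similarity
transforms that align fundus images align thickness maps. Features are the
all-rings average (mean over all valid annulus pixels), four quadrant
means over 90° sectors centered on the temporal, superior, nasal, and
inferior meridians, and twelve 30° clock-hour means, hour 12 centered on
the superior meridian with hours increasing clockwise in the right-eye
(OD) presentation; left-eye maps are mirrored about the vertical axis
before sector assignment so labels follow the OD convention. Sector
boundaries are half-open so every pixel belongs to exactly one quadrant
and one hour. The angular position of the first a-scan (`theta0_deg`) is
map metadata with default 0° at the temporal meridian.

Before registration, features are computed per session on each full
annulus. After registration, all of a subject's rasters are warped into
the reference frame by their estimated corrections and features are
computed on the *common* overlap region (pixels valid in every aligned
raster), so every session averages exactly the same retinal area.

## Longitudinal mixed-effects models

Three analyses, all linear mixed-effects models with a per-subject random
intercept, fitted by REML through `nlme` (the package historically used
for this design); slope p-values use within-group denominator degrees of
freedom, `nlme`'s convention:

1. **Paired comparison** (`fit_comparison_model`): response = precision or
   recall, fixed effects intercept + γ·reg where `reg` indicates
   with/without registration (or which algorithm). γ is the registration
   benefit.
2. **Trend** (`fit_trend_model`): response = a feature value, fixed slope
   over days since baseline (μm/day). The slope p-value is the test for
   longitudinal change; in healthy eyes over ~30 weeks the truth is no
   change, so any significant slope without registration is an artifact.
3. **Residual magnitude** (`compare_residual_magnitudes`): response =
   |conditional residual| from the trend fits on identical (subject, day)
   keys, design as in (1). A negative slope means registration reduced
   unexplained measurement variation. Absolute (not squared) residuals are
   used, matching the "magnitude of residuals" framing.

With only three subjects the random-intercept variance can estimate at
the boundary and REML can fail (it always does on exactly noise-free
inputs); the fit then degrades to a fixed-intercept linear model with a
warning instead of failing. No multiple-testing correction is applied
across the 17 features by default — standard reporting practice for this
feature set — but Holm correction is available via a flag.

## The synthetic-data generator

The generator replaces the unavailable primate data with scenes whose
geometry is controlled and whose ground truth is known exactly. It aims
for *geometric* realism (what registration sees), not photometric or
speckle realism.

* **Vessel trees**: a configurable number of main vessels (default 5,
  mirroring the "five widest vessels" segmentation rule) radiate from a
  central disc region as smooth random walks with a radial pull, taper as
  they go, and branch with a per-step probability. Widths are specified in
  canonical-frame pixels and scaled with the working frame so physical
  vessel width is frame-invariant; default specs give a vessel pixel
  fraction of roughly 5–12%.
* **Fundus images**: a smooth background with broad illumination blobs, a
  bright ONH disc, mild spatially correlated texture, and vessels rendered
  ≥ 20 gray levels darker than their local background. The texture is what
  gives the MI surface enough structure to localize rotation precisely.
* **Thickness maps**: the angular profile is a periodic cubic spline with
  knots at the four quadrant-center angles, but the knot values are
  obtained by solving a small linear system so that the *quadrant means*
  of the profile equal the specified values (81.65 / 112.17 / 82.74 /
  132.22 μm for temporal / superior / nasal / inferior by default, the
  healthy-primate scale) — a spline through the means themselves would
  overshoot them after averaging. This produces the clinically typical
  superior/inferior double hump with steep gradients near the quadrant
  transitions, the sectors most sensitive to misalignment. Noise has two
  components: per-sample Gaussian noise (default 6 μm) and a per-session
  global offset (default 2.5 μm) modeling instrument reproducibility
  error — axial calibration and segmentation shift a whole acquisition
  together. The session-level term is what gives heavily averaged features
  (the all-rings mean over 10⁴ samples) a realistic noise floor; without
  it their trend tests operate at a microscopic scale no real instrument
  attains.
* **Sessions**: each subject has one reference rendering; a session is
  that rendering warped by a random ground-truth misalignment. Fundus and
  vessel rasters are warped; the thickness map is produced by sampling the
  analytic thickness field through the inverse transform on the nominal
  ring-scan grid, which is the render-then-warp construction minus one
  raster resampling error and models what a misplaced scan ring actually
  measures.
* **Misalignment model**: i.i.d. zero-mean Gaussian translation (SD 5 px)
  and rotation (SD 3°) with log-normal scale (SD 0.02) — magnitudes well
  inside the registration search bounds — *plus* a small linear temporal
  drift (defaults 0.03 px/day in x, −0.02 px/day in y, 0.03°/day in
  rotation, i.e. about 6 px and 6° over a 30-week study). The drift term
  is essential to the phenomenon under study: purely i.i.d. misalignment
  inflates feature noise but leaves the trend test calibrated, producing
  no excess of spurious slopes; drifting misalignment (progressive change
  in eye positioning over a long study) is what converts steep-gradient
  sectors' misalignment error into apparent longitudinal change. Draws
  that fall outside the registration search bounds are rejected and
  redrawn (counted on the returned series).
* Everything is bit-reproducible for a fixed seed, with per-subject and
  per-session streams derived from the root seed.

What passing tests on these scenes do **not** show: performance on real
OCT fundus projections (speckle, shadowing, segmentation errors in the
vessel masks), robustness to pathology-driven thickness change, or
behavior under misalignments outside the stated search bounds.

## Problem sizes used by the tests and the acceptance script

Simulation studies run in a 256 × 256 working frame (the canonical 512 ×
512 is supported throughout; all search grids are specified in pixels and
used unchanged). Transform-recovery experiments use 50 seeded pairs per
algorithm; the registration-benefit series uses the 3-subject 8/16/16
design over 210 days; the end-to-end trend study uses 20 seeded 3-subject
6/8/8 series, registered with the vessel-based algorithm using 256
log-radius bins at the fine level (sector features are insensitive to the
~1% scale quantization this implies, and it keeps the 380 registrations
affordable). The acceptance script repeats the same computations at 20
recovery pairs and 8 trend-study seeds. Monte-Carlo checks of the mixed
models use 200 replicates for slope recovery and 500 for test size.

## Known limitations

* Exhaustive grid search is faithful but slow; no gradient or simplex
  optimizer is provided by design.
* The LPCC fine level re-estimates rotation and scale as well as
  translation; if the coarse estimate is wrong by more than the fine
  window can absorb (±4 px origin, ±32 log-radius bins), the result is
  flagged rather than repaired.
* Sector features assume the ONH is at the raster center; decentered
  annuli are out of scope.
* The generator's drift defaults are plausible, not calibrated — the
  original study does not report the magnitude of inter-session
  positioning drift.
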