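---
title: "Image-based pipette volume monitoring: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based pipette volume monitoring: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipvision)
```

## The monitoring problem

Point-of-care diagnostic instruments aspirate reagents through a disposable
conical pipette tip driven by a stepper-motor pump. The commanded volume is
proportional to the motor step count, but wear, part failure and user error
can make the delivered volume drift away from it, silently corrupting assay
results. A fixed, inexpensive camera pointed at the tip can monitor this:
the instrument controls illumination and uses a matte background, so the
imaging conditions are stable enough that deliberately simple image
processing — fixed thresholds and binary projections, cheap enough for an
embedded host — is reliable.

`tipvision` implements the full chain: segmentation of the red reagent
column, measurement of its projection support length, cube-linear
calibration against pump steps, inverse step estimation, and the
pass/fail malfunction decision, plus the tip/holder localisation checks
used to catch a missing or misaligned tip.

## The measurement model

**Segmentation.** The reagent is dyed red; the background and tip are grey.
Per pixel the pipeline computes the BT.601 luminance
$Y = 0.299R + 0.587G + 0.114B$ and the *pure red* difference
$P = \max(R - Y, 0)$. For any grey pixel ($R = G = B$) the weights sum to
one, so $P = 0$ exactly; for the default reagent colour (180, 30, 30),
$P = 105$. $P$ is 3×3 median-filtered and binarised with a strict fixed
threshold ($P > t$, default $t = 40$).

Three conventions are deliberately pinned down because they change results
at the pixel level:

* luminance rounds half-up (`floor(x + 0.5)`), so segmentation is
  reproducible across platforms regardless of the host's rounding mode;
* the median filter replicates edge pixels, preserving the image shape;
* binarisation is strict (`>`), so a pixel exactly at the threshold is
  background.

The colour-difference sign is a configuration switch
(`red_sign = "r_minus_y"` by default). With this orientation the reagent
maps to large positive values and a single upper-side threshold is
meaningful; the opposite convention is available for devices whose optics
invert the contrast.

**Volume length.** The mask is projected horizontally (each row collapses
to its foreground count) and the *support length* — the number of rows with
a non-zero count — is the volume length $L$ in pixels. The support counts
all non-zero positions rather than the first-to-last span: gaps caused by
segmentation noise therefore shorten $L$, and the upstream median filter is
what keeps such gaps from occurring. Localisation uses the same machinery:
the tip position is the support centre of the column profile (floor of the
midpoint for even spans, a deterministic tie-break), the holder top is the
first non-zero row of a dark-pixel mask. An empty mask yields `NA` — an
"absent" detection outcome, not an error.

**Calibration and decision.** The tip is a cone, so the aspirated volume is
$V = \tfrac{\pi \tan^2\theta}{3} h^3$ with $h$ the column height: $L^3$ is
linear in the commanded steps $s$. Calibration fits $L^3 = a s + b$ by
ordinary least squares (via `stats::lm`), recording slope, intercept and
$R^2$; estimation inverts it analytically, $\hat s = (L^3 - b)/a$. The
direction of the regression (cubed length on steps, not steps on cubed
length) is fixed so the printed equation matches the calibration plots and
the inversion is exact. A pump check fails when $|\hat s - s|$ *strictly*
exceeds the bound — by default 5 % of the commanded steps, the inaccuracy
specification class of such dispensers; an absolute-steps bound is also
available. Precision at a step level is summarised by the RMS deviation of
$\hat s$ from the *true* commanded steps (not from the sample mean — the
mean error is assumed to converge to zero with more replicates), and by
that deviation as a percentage of the commanded steps.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `threshold` | 40 | 8-bit intensity | matte backgrounds give $P \approx 0$–10, reagent $P \gtrsim 100$; 40 sits in the wide gap |
| `red_sign` | `r_minus_y` | — | reagent maps to high positive values |
| `holder_luminance_threshold` | 140 | 8-bit intensity | holder ($Y \approx 80$) vs background ($Y \approx 200$) |
| `bound_mode`, `bound_value` | relative, 5 | % of commanded steps | dispenser inaccuracy specification class |
| `tip_roi`, `holder_roi` | scene geometry | px | the camera is rigidly mounted; two separate ROIs so the holder never enters the volume measurement |

ROIs are 1-based inclusive pixel ranges, matching R matrix indexing. The
configuration can be read from a YAML file (`read_pipeline_config()`);
the calibration persists as plain JSON so firmware can consume it without R.

## The synthetic-scene generator

Real frames from an instrument are not distributable, so validation rests
on a generator that emulates exactly the conditions the method assumes:
an upright cone (apex down) holding a red liquid column on a matte grey
background, a dark holder bar, optional vertical illumination ramp, and
additive Gaussian sensor noise (clamped, per channel) — with the full
geometry recorded as ground truth (liquid top row, apex row, real-valued
column height, per-pixel mask).

Defaults, chosen once as a realistic mid-range geometry: 340×320 frame,
apex at (310, 160), 0.184 µL per pump step, 34.5 px/mm magnification — a
640-step aspiration then fills ≈ 240 rows, and sweeps over 40–640 steps
cover column lengths ≈ 95–240 px, similar to what a close-up camera module
sees. The cone half-angle is 30°, wider than a physical tip: in pixel space
this guarantees every liquid row above the apex is at least 3 px across, so
the median filter — which by design erases structures thinner than its
window — can bite only the single apex pixel. The measured volume length is
therefore within 1 px of the geometric truth, which is the resolution limit
of the method itself, not an artefact of the generator. The cube law is
unaffected by the angle.

Determinism is part of the contract: every render takes a seed, sweeps
derive per-element seeds from a master seed, and rendering restores the
caller's RNG stream. Two renders from the same spec are bit-identical.

What the generator does **not** emulate: meniscus curvature and refraction,
specular highlights on the tip wall, lens distortion, motion blur, and
pump-mechanism replicate scatter (at realistic sensor-noise levels the
thresholded support is stable, so replicate renders of the same volume give
identical lengths — real replicate scatter comes from the pump, which the
failure-injection modes emulate only as systematic under-aspiration).
Passing the synthetic suite therefore demonstrates the correctness of the
algorithmic chain and its calibration algebra, not robustness to optical
effects the device's controlled imaging is designed to exclude.

## Numerical and design choices

* **Replicate statistics.** Sample SD ($n-1$); CV reported in percent
  (`100·sd/mean`). The bundled reference tables label their CV column as
  published; recomputing CVs from published *rounded* means and SDs can
  differ from a published CV row by one unit in the last printed digit
  (double rounding), which is the agreement the tests assert.
* **Degenerate inputs.** Empty ROI, out-of-bounds ROI (error names the
  violated edge), single-replicate SD, all-equal step levels and zero-slope
  inversion are errors; an empty mask is a legal "absent"/zero outcome.
* **Negative step estimates** (length below the calibrated range) are
  returned with a warning rather than clamped, so callers can treat them as
  an implausible-volume signal.
* **OLS** is delegated to `stats::lm`; the test suite checks it against an
  independent normal-equations solver to 1e-9 relative, and checks $R^2$
  invariance under affine rescaling of either axis.
* **Problem sizes.** Tests use a reduced 120×100 scene for per-operation
  checks and the full 340×320 geometry for end-to-end runs: a 20-point
  noise-free closure sweep, a 16-level × 5-replicate noisy calibration with
  held-out step recovery, and repeated under-aspiration checks — small
  enough to run in seconds while covering the full operating range.

## Known limitations

* The method needs a dyed reagent with a colour separable from the
  background by a single linear channel difference; colourless liquids are
  out of scope.
* Volume resolution is set by pixel quantisation of the column height; at
  the bottom of the range (short columns) a ±1 px error is a larger
  relative volume error, which is why step recovery is specified over the
  upper part of the range.
* Columns only a few pixels tall can be erased entirely by the median
  filter — the image-processing analogue of a minimum detectable volume.
* The calibration is strictly cubic (conical tip). Tips with a cylindrical
  upper section would need a piecewise volume model, deliberately excluded.
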