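---
title: "Measuring optic nerve head area on OCT B-scans, and how much to trust it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring optic nerve head area on OCT B-scans, and how much to trust it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhrel)
```

## The measurement

A spectral-domain OCT B-scan is a 2-D grid of backscatter intensities:
rows are axial depth (increasing downward, into tissue), columns lateral
position. Each image carries its own scaling factors in μm per pixel,
axial and lateral, and **every geometric computation in this package
happens in micrometres after conversion through those factors** — the
scales are mandatory metadata, never defaulted, because they differ
between devices and even between images.

Two boundaries define optic-nerve-head (ONH) morphometry:

* the **inner limiting membrane (ILM)**, the retinal surface, which is
  pushed up toward the vitreous when the nerve head swells, and
* **Bruch's membrane (BM)**, delineated as two wings — nasal and
  temporal — because its medial margins are shadowed beneath the elevated
  nerve and cannot be traced there.

Semi-manual segmentation represents each boundary as an ordered list of
rater-placed control points (fractional pixel coordinates allowed: cursor
placement is sub-pixel) with a curve fitted through them; the rater adds,
removes or moves points until the curve tracks the anatomy. The boundary
is single-valued in the lateral coordinate, so two control points at the
same abscissa are an invariant violation, not a merge.

The BM wings are joined by an exact straight line between the medial
margins (the last point of the left wing, the first of the right), giving
a continuous bridged boundary. The **cross-sectional area score** is then

$$A \;=\; \int_{c-w}^{c+w} \big(y_{BM}(x) - y_{ILM}(x)\big)\, dx,$$

with the window half-width $w$ = 2.85 mm (a 5.7 mm diameter window) and
$c$ defaulting to the lateral midpoint of the image, since acquisition
centres these scans on the nerve head; an explicit `center_x` override is
available. The integrand is kept signed: if a delineation crosses (ILM
below BM), the crossing region *reduces* the area and a warning is
raised — silently clipping would hide a segmentation error.

## The curve fit

No published description pins down the interpolation family used by the
original segmentation tools, so the choice is the package's own: a
**shape-preserving piecewise-cubic Hermite interpolant with
Fritsch–Carlson slopes**. Node slopes are the mean of the adjacent secant
slopes, forced to zero wherever the secants change sign (local extrema of
the control points), then limited to the circle $\alpha^2+\beta^2 \le 9$,
which is sufficient for monotonicity on every monotone data interval.
Consequences that matter for an anatomical boundary:

* the curve passes through every control point exactly;
* between consecutive control points with monotone ordinates the curve
  stays inside the two ordinates — no ringing, unlike an unconstrained
  cubic spline, which can overshoot badly between sparse points;
* collinear control points reproduce a straight line exactly.

The interpolant is implemented in the package rather than delegated:
the standard library's monotone-spline mode guarantees monotonicity only
where the data are monotone and does not zero the slope at local extrema,
so it can overshoot the local ordinate range precisely where an ONH
boundary turns (the cup, the bump shoulders). A dense-grid property test
enforces no-overshoot on random control polygons.

One locality caveat, verified by test: because any $C^1$ shape-preserving
cubic derives a node's slope from *both* adjacent secants, editing
control point $i$ perturbs the curve on $[x_{i-2},\,x_{i+2}]$, not merely
between the immediate neighbours. That is the tightest locality any such
interpolant can offer.

## Agreement statistics

**Segmentation differences.** Disagreement between two delineations of
the same scan is the mean over a uniform lateral grid (intersection of
the two supports) of the *absolute* axial difference, reported per scan
in μm and pixels. Absolute values are the right choice for a per-scan
disagreement magnitude: signed differences between raters would centre
near zero and understate disagreement. BM comparisons use the bridged
boundary, so inconsistent margin identification propagates into the
interpolated sub-nerve line exactly as it does into the area.

**Limits of agreement.** Mean ± 1.96 × SD (n − 1 denominator) of a set
of values. Outliers are records strictly above the *upper* limit only —
absolute differences cannot meaningfully breach a lower bound — and a
record exactly at the bound is not flagged.

**ICC.** Two-way random, absolute agreement, single measure — ICC(A,1):
subjects and measurers (sessions, raters or devices) are both random, and
systematic measurer offsets count against agreement. From the complete
n × k table's ANOVA mean squares,

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$

The mean squares are computed from definitional sums of squares inside
the package; an independent `aov()`-based computation serves as the test
oracle. Single-measure is chosen because each reported comparison uses
one measurement per measurer per eye; the average-measure variant
ICC(A,k) is exposed via `type = "average"`. A zero-total-variance table
is an explicit error, not a silent `NaN`. Confidence intervals for the
ICC are deliberately out of scope.

**Bland–Altman.** Differences follow the fixed convention first argument
minus second. The bias CI is $t_{0.975,\,n-1}\, s/\sqrt{n}$ around the
mean difference; each agreement limit gets the standard
$t_{0.975,\,n-1}\, s\sqrt{3/n}$ interval.

## The synthetic study

Because no clinical scans ship with the package, a phantom generator
produces studies with the statistical structure the analysis assumes.

**Geometry.** A phantom eye is a flat BM at depth $d_{BM}$ with a
sub-nerve gap, and an ILM at baseline depth $d_{ILM}$ elevated by a
Gaussian bump $a\,e^{-(x-c)^2/2\sigma^2}$ (elevation means *smaller*
depth). Its area has the closed form

$$A = 2w\,(d_{BM}-d_{ILM}) + a\,\sigma\sqrt{2\pi}\,\operatorname{erf}\!\big(w/\sigma\sqrt{2}\big),$$

which is the independent oracle for the trapezoidal pipeline: on the
default discretisations the two agree to about $10^{-4}$%. The default
population is ten eyes — four non-swollen (amplitude 0, retinal thickness
285–330 μm) and six swollen (amplitudes 200–650 μm, σ 700–900 μm) —
calibrated so ground-truth areas span ≈1.62–3.29 mm², the clinically
reported range for a mixed papilledema cohort. The baseline ILM depth is
700 μm, placing the elevated surface safely inside the image; the
constructor rejects amplitudes that would lift the ILM out of frame.

**Raters.** Placement error is modelled as a stationary Gaussian process
along the scan (squared-exponential correlation, default length 500 μm)
rather than independent per-point noise, for two reasons. Scientifically,
rater disagreement is spatially structured — it concentrates in regions
like the cup and the shadowed sub-nerve BM, not at isolated pixels.
Numerically, a correlated process preserves the marginal error sd through
the curve fit: with independent per-point noise the fitted curve's
variance between control points is attenuated by interpolation, and the
folded-normal relation below would be biased low by ~20%. Each rater
carries a rater-level process (sd `axial_noise_sd`, default 8 μm) drawn
once per scan and shared across that rater's sessions, plus an
independent session-level process (sd `session_noise_sd`, default 2 μm);
medial BM margin choice gets lateral error (sd 50 μm), also a rater-level
trait. With this decomposition repeat sessions agree much better than
raters, as observed clinically. Two independent raters with noise sd
$\sigma$ differ pointwise by $N(0, 2\sigma^2)$, so the mean absolute ILM
difference estimates $2\sigma/\sqrt{\pi}$ (≈9.03 μm at $\sigma=8$) —
the pipeline recovers $\sigma$ to within a few percent over 30 scans.
Gross boundary confusion (e.g. tracing the vitreous interface instead of
the ILM) is available as an explicit mechanism
(`confusion_prob`/`confusion_offset`) for studying outlier flagging, but
is off by default: it is an episodic failure mode, not part of the
baseline noise hierarchy.

**Devices.** Each device has its own pixel grid and declared scaling,
a systematic axial offset, and multiplicative *calibration errors* on the
declared scales (defaults ±2%, same sign on both axes per device). The
offset is deliberately inert for areas: shifting both boundaries equally
leaves the integral unchanged (verified as the translation-invariance
law), so offsets only move absolute depths. What actually separates
devices is calibration: over a window fixed in reported units, an axial
scale error multiplies the whole area by its factor exactly, while a
lateral error rescales only the elevation-bump contribution (the flat
rectangle spans the window regardless of lateral stretch). The same-sign
±2% defaults therefore yield inter-device area spreads that dominate
rater noise, reproducing the clinically observed ordering
*intra-rater < inter-rater < inter-device* for maximum area differences,
with all pooled ICCs above 0.9 and ordered the same way.

**Reproducibility.** All randomness chains from one study seed through
deterministic per-entity sub-seeds, so `generate_study()` reproduces a
study byte for byte, including the manifest.

**What the phantoms do not emulate.** Real speckle texture, vessel
shadows, acquisition averaging settings, globe-shape variation of BM,
motion artefacts, and rater fatigue. Passing the synthetic suites shows
the *computational chain* is correct and that the agreement statistics
respond lawfully to known noise structures; it does not certify any
particular clinical device pairing.

## Pipeline conventions and numerical choices

* Pixel indices are 0-based; the physical origin is the centre of pixel
  (0, 0). Only coordinate differences enter any formula, so the origin
  choice is observationally irrelevant.
* Default sampling step 5 μm for boundary evaluation and integration:
  finer than any device's lateral pitch, making device grids
  commensurable; halving it changes smooth-phantom areas by well under
  0.05%. The realised grid step is the largest value ≤ the request that
  divides the support evenly, so window endpoints are always sampled.
* Trapezoidal integration of the boundary gap; area additivity over
  adjacent windows holds exactly when the step divides both.
* A zero-width BM gap degenerates to direct concatenation of the wings;
  the bridge is exact linear interpolation between the margin depths and
  is continuous at both junctions by construction.
* Summaries are stratified by protocol (line vs radial) and never pooled;
  device comparisons run on radial scans only, where positioning is
  comparable. Quality exclusion is manifest-driven (a `quality` column),
  since vendor signal indices are not recomputable from pixels; every
  exclusion is logged.
* Inter-device comparisons are made on areas (differences, ICC,
  Bland–Altman), not on boundary curves: two devices image the same eye
  on different pixel grids and scans, so a per-location axial difference
  is not defined across devices the way it is within a scan.
* Sessions within a rater are ordered lexicographically by session id;
  the first session per rater enters inter-rater and inter-device
  comparisons.

## Problem sizes

The shipped tests and the acceptance script use: 100 random phantoms for
the area oracle, 500 random tables for the ICC oracle, 30 scans × 2
raters for noise recovery, and the full default study (10 eyes × 3
devices × 3 raters + 1 repeat session = 120 segmentations on 30 scans)
for the hierarchy checks — sizes chosen to keep Monte-Carlo error several
times smaller than the tolerances they are checked against.

## Known limitations

* The ICC is reported without confidence intervals or hypothesis tests.
* The curve-fit family is a reasoned choice, not a reconstruction of any
  specific legacy tool; other shape-preserving interpolants would give
  areas differing at the sub-0.1% level on smooth boundaries.
* The generator's device calibration errors are set to reproduce the
  qualitative agreement ordering; absolute inter-device differences in
  any real device pair depend on calibrations no one publishes.
* Vendor raw formats (`.img`, `.OCT`, `.vol`) are not parsed; scans enter
  through the TIFF + JSON interchange after external conversion.
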