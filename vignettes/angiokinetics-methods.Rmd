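---
title: "Pixel-level kinetics of video fluorescein angiography: methods and design"
author: "angiokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel-level kinetics of video fluorescein angiography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiokinetics)
```

## The problem

Conventional fluorescein angiography grades a handful of snapshots taken
seconds to minutes after dye injection — essentially a qualitative, almost
binary readout. Video angiography (e.g. 30 frames/s for 30 s from the start
of an intravenous fluorescein bolus) records the full transit: choroidal and
arterial filling, capillary perfusion, venous return, and decay toward a
plateau. `angiokinetics` quantifies that transit at every pixel and turns
the result into maps that localize abnormal dye retention, such as the
leakage caused by focal laser photocoagulation of the blood–retinal
barrier.

The pipeline has five stages, run in order by `run_pipeline()` or
individually:

1. **Registration** — translational alignment by cross-correlation to a
   reference frame.
2. **Temporal filtering** — PCA reconstruction (control-type data) or a
   3-point moving median (high-variance injury data).
3. **Kinetics extraction** — per-pixel half-rise, peak, half-fall (with
   capping), and offset amplitude.
4. **Regional summaries** — vessel class × quadrant × eccentricity-zone
   means ± SEM.
5. **Anomaly mapping** — per-pixel standard-deviation units from the
   eye-wide mean, thresholded at 1–4 SD.

A synthetic phantom generator with exact ground truth closes the loop for
every stage.

## Per-pixel kinetic parameters

For a pixel's intensity series \(y(t)\) (time zero at infusion start):

* **baseline** \(b\): mean of the first `baseline_window_s` (default 1 s,
  before dye arrival);
* **peak** \(p\): the series maximum, at `peak_time_s`;
* **offset amplitude**: mean of the last second of recording, reported as
  `offset_pct` \(= 100\,(\mathrm{offset}-b)/(p-b)\), clamped to [0, 100];
* **half-rise**: first upward crossing of \(b + (p-b)/2\) before the peak,
  linearly interpolated between frames;
* **half-fall**: first downward crossing of
  \(\mathrm{offset} + (p-\mathrm{offset})/2\) after the peak, interpolated;
  if the series never crosses that level, `half_fall_s` is recorded as the
  nominal duration (e.g. 60 s) and flagged `capped`.

Design choices a user should know about:

* **Baseline-referencing.** The 50% rise level is referenced to the
  pre-dye baseline, not to absolute zero, making all timing parameters
  invariant under positive affine intensity maps (camera gain/offset).
  The half-fall level is referenced to the measured offset amplitude, so
  it needs no baseline.
* **Common clock.** Half-rise and half-fall are both reported as absolute
  times from infusion start, which is the only convention under which
  typical values (half-rise ≈ 7–9 s, half-fall ≈ 11–14 s) are coherent.
* **First-crossing rule.** With residual noise a level can be crossed more
  than once; the first crossing is used on both limbs.
* **Flat pixels** (zero range, or maximum inside the baseline window) are
  marked invalid rather than zero-filled, so population statistics are not
  diluted by non-perfused or blank pixels.
* **Operational vs asymptotic offset.** Because the offset is *measured*
  as the last recorded second, a profile that has not finished decaying
  carries a small difference between the measured offset and the true
  plateau, which also shifts the half-fall level slightly. This is a
  property of the measure itself, not an implementation artifact; the
  closed-loop tests therefore compare jittered-and-registered extraction
  against the identical extraction on the exact noiseless curves.

## Registration

Each frame is mean-centred and circularly cross-correlated with the
mean-centred reference frame in the frequency domain; the argmax gives the
frame's (dy, dx) translation. Only translation is corrected: rotation,
scale and shear corrections buy little for fundus video and are left to
temporal filtering, and uncovered borders are *invalidated, never
interpolated*, so kinetics are computed exclusively on observed data.

Numerical details:

* The reference defaults to the frame with maximal total intensity — a
  proxy for "all vessels filled" (mid-transit). Ties take the earliest
  frame. A user override is accepted.
* Ties at the correlation maximum break toward the smaller shift
  magnitude, then lexicographically on (dy, dx); shifts are bounded by
  H/4, W/4 by default.
* Integer-pixel shifts are the default; `subpixel = TRUE` refines the peak
  with a separable three-point quadratic fit.
* **Variance floor.** A frame whose centred variance is below
  `min_variance_frac` (default 2%) of the reference's carries essentially
  no structure — in practice the pre-arrival darkness of a noisy
  acquisition — and registering it would lock onto noise. Such frames
  keep shift (0, 0) and are counted in a message. For noise-free data
  (e.g. synthetic closed-loop studies) set `min_variance_frac = 0`: every
  frame with any structure then registers exactly.
* A frame with exactly zero variance gets shift (0, 0) with a warning.

## Temporal filtering

**PCA.** Every valid pixel is one observation described by T frame
variables. Variables are centred by the per-frame mean over pixels and
decomposed by an exact eigendecomposition of the T × T covariance matrix
(deterministic; each component's sign is fixed so its largest-magnitude
element is positive). No per-pixel standardization is applied: raw
intensity profiles keep amplitude information in the scores, which is what
makes the first component "the profile shape that fits the most pixels".
Reconstruction with the k = 2 leading components (or
`k = "auto95"`, the smallest k reaching 95% cumulative variance) removes
residual-motion artifacts and noise; with all components it reproduces the
input to float tolerance.

**Moving median.** Laser-injured fields violate the low-rank assumption —
lesion pixels follow their own diverse time courses — so the injury preset
applies a centred 3-point moving median per pixel instead. The edge sample
is conceptually replicated once so the window is always three long, which
leaves the endpoints unchanged. The filter rejects single-frame spikes and
never produces values outside the local 3-point range.

## Regions and summaries

Vessel masks are **inputs** (manual tracings); no automatic segmentation is
shipped, deliberately. Precedence on overlap is ONH > artery > vein, and
the capillary/choroid class is the complement. Quadrants are four
90° sectors centred on the ONH with a configurable superior-axis angle
(fundus orientation depends on eye and camera; default superior =
image-up). Eccentricity zones come from micrometre distance to the ONH
centre — inner ≤ 640 µm, outer ≤ 1280 µm by default, boundaries closed on
the inner side; an arbitrary radius vector supports finer (e.g. 200 µm)
annuli. Cells are summarized as mean ± SEM; empty cells are reported with
n = 0, single-pixel cells get SEM 0 with a warning, and half-fall rows
carry the cell's capped fraction.

## Anomaly maps

For a chosen parameter map (half-fall or offset), each pixel is expressed
as \(z = (x-\mu)/\sigma\) with µ and σ estimated over an explicit
`included_mask` — typically the capillary/choroid field with large
vessels, the ONH, and (for half-fall) capped pixels excluded, the latter so
that a 60 s cap cannot inflate the null spread. The level map stores the
largest threshold k ∈ {1..4} with z ≥ k. The signed positive-tail
convention is the default because injury *prolongs* half-fall and
*elevates* offset; `two_tailed = TRUE` uses |z|. µ and σ are computed in a
single pass without iterative outlier re-exclusion. Global indices per
threshold — abnormal pixel count, area in µm², number of 8-connected
components, largest component area — support longitudinal monitoring.

Half-fall and offset play complementary roles: the half-fall map singles
out pixels whose fluorescence keeps rising (no decay by the end of the
sequence ⇒ capped at the nominal duration), while the offset map flags all
areas of excess end-of-sequence fluorescence, including retained dye that
decays only minimally. The within-image z-score assumes the abnormal
fraction of the included field is small; if lesions occupy a large share
of the field they inflate σ and mask themselves (a known limitation —
compare against a baseline sequence in that case).

## The synthetic phantom

`default_control_spec()` renders 30 s at 30 frames/s over a 96 × 96 px
field at 31 µm/px (≈3 mm of posterior pole, matching a rodent fundus
camera's view centred on the optic nerve head). Eight curved radial
vessels alternate artery/vein around a 6 px ONH disc. Class kinetics are

| class | half-rise (s) | peak (s) | half-fall (s) | offset | peak amp (a.u.) |
|---|---|---|---|---|---|
| artery | 7.6 | 9.5 | 11.9 | 0.35 | 200 |
| vein | 8.6 | 10.5 | 13.9 | 0.55 | 200 |
| capillary/choroid | 7.8 | 9.8 | 11.8 | 0.40 | 60 |

so veins rise ~1 s later and decay ~2 s later than arteries, all classes
plateau before 25 s, and the capillary layer is modulated by a smooth
spatial amplitude field (choroidal texture). Per-frame jitter (SD 1 px,
integer translations — the same motion model the registration corrects)
emulates breathing; additive gaussian noise (SD 5 a.u., clipped at zero)
emulates camera noise. `default_injury_spec()` extends recording to 60 s
and places four circular leak lesions of radius 5 px (~310 µm diameter, a
~3× halo around a 100 µm laser burn) between the major vessels, one per
retinal sector: two *continuous-rise* lesions (accumulation through the
whole sequence) and two *minimal-decay* lesions (retention with ~20%
decay). Lesion radii are kept small relative to the field because the
within-image z-score method itself assumes a small abnormal fraction (see
above). The intensity scale is arbitrary (camera units); `peak_amp`
defaults are conventional.

The canonical profile is a logistic rise times an exponential
decay-to-plateau,
\[
f(t) = A\,\frac{\min(r(t), r(t_p))}{r(t_p)}\; d(t),\qquad
r(t) = \mathrm{logis}(k\,(t - t_{hr})),\qquad
d(t) = \phi + (1-\phi)\,2^{-(t-t_p)/(t_{hf}-t_p)}\ (t > t_p),
\]
chosen because any smooth unimodal-with-plateau form is compatible with
observed transits and this one makes half-rise, half-fall, and offset
analytically invertible for testing: the half-decay level is crossed
exactly at \(t_{hf}\), and the 50% rise crossing sits at \(t_{hr}\) up to a
term that vanishes as the rise saturates before the peak. The default
steepness k = 2.2 s⁻¹ gives a 10–90% rise of ≈2 s. Closed-loop recovery to
within one frame interval therefore holds on the physiologic domain where
the rise saturates ≥ ~1.7 s before the peak and the decay plateaus before
the final second — the regime a 30 s acquisition is designed to capture;
outside it (e.g. a decay half-time comparable to the remaining recording)
the *operational* parameters differ from the asymptotic ones by
construction, for any analysis method.

What the phantom deliberately does **not** model: physiologic
hemodynamics, realistic vessel-tree growth, photobleaching/quenching,
non-gaussian camera noise, rotation/scale/shear motion, and illumination
falloff. Passing closed-loop tests therefore demonstrates the analysis is
correct *given* the translation-plus-noise acquisition model, not that the
model captures every property of real recordings.

## Problem sizes and numerical conventions

The test suite mostly runs a compact 48 × 48 px, 12 s phantom with
accelerated kinetics (chosen so that all class profiles saturate and
plateau within the short window), and the full default 96 × 96 × 900-frame
phantom for the headline PCA and lesion-recovery checks. Everything is
deterministic given a seed: rendering seeds `set.seed(spec$seed)`, PCA
uses an exact eigendecomposition, and registration ties have a fixed
tie-break. Pixel coordinates are (row, col), 1-based, row 1 at the top;
µm distances are Euclidean pixel distances × `um_per_px`. Frame i is at
time (i − 1)/frame-rate, frame 1 at infusion start.

## Known limitations

* Translation-only registration leaves rotation/scale/shear uncorrected
  (by design; temporal filtering absorbs small residuals).
* Pre-arrival frames of noisy data cannot be registered (variance floor);
  their misalignment is irrelevant to baselines (dark) but means the very
  earliest transit is not stabilized.
* The half-fall of a nearly-flat decay is noise-dominated under the
  first-crossing rule; the offset map is the robust detector for
  minimal-decay retention.
* Within-image z-scoring self-masks when abnormal area is large.
* µm scale must be user-supplied (camera calibration); no default is
  meaningful across instruments.
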