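---
title: "Diameter tracking for pressure myography: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diameter tracking for pressure myography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myographr)
```

## The measurement problem

In a pressure myograph an isolated artery is cannulated, pressurized and
imaged while drugs or pressure steps are applied; the readout is the time
course of its outer diameter (OD), inner diameter (ID) and wall thickness.
`myographr` implements the measurement core of such a rig for pre-recorded
image series: it samples 1-D intensity profiles across the vessel, locates
the wall edges on each profile, aggregates profiles into per-frame diameter
records, applies temporal quality control, and exports results in a
two-file CSV convention together with an overlay stack. A synthetic vessel
phantom with exactly known geometry backs every algorithm with ground
truth.

## Coordinate conventions

All frame geometry uses continuous 0-based coordinates with `x` the column,
`y` the row, and integer positions at pixel centres; sub-pixel positions
are real numbers in this frame. Positions along a profile are distances in
pixels from the first sample (first sample = 0). The only place these
conventions meet R's 1-based arrays is inside the bilinear sampler.
`detect_peaks()`, which operates on plain R vectors rather than image
geometry, returns ordinary 1-based vector indices.

## The edge-detection model

A track line yields one or more intensity profiles `F(x)` sampled at unit
spacing by bilinear interpolation. An edge is defined as the *steepest
point* of the intensity transition, i.e. an extremum of `dF/dx`, not a
half-maximum crossing. The pipeline per profile is:

1. moving-average smoothing (window `smooth_window`);
2. differentiation by central differences (one-sided at the ends);
3. peak detection on `+dF/dx` and `-dF/dx` separately, with topographic
   prominence filtering and minimum-separation suppression;
4. sub-pixel refinement of each retained peak.

For **brightfield** (dark walls on a bright background) the outer edges are
the leftmost qualifying falling edge and the rightmost qualifying rising
edge; the inner (lumen) edges are the strongest opposite-sign peaks
strictly inside the outer pair, each restricted to its half of the vessel.
Inner edges are reported absent when no qualifying candidate exists, and a
refined inner candidate that lands out of order is dropped rather than
reported inconsistently.

For **fluorescence** and **B-mode ultrasound** the walls are bright bands
on a dark lumen/background. Here the band apexes are found first, by peak
detection on the smoothed intensity itself with a prominence threshold of
`band_prominence` times the profile dynamic range; the leftmost and
rightmost bands are taken as the two walls and each edge is then the
steepest point of the corresponding flank (outer flank rise / inner flank
fall for the left band, mirrored on the right). The band-then-flank rule is
a design choice of this package: it makes the detector insensitive to
uniform intensity offsets and to the exact band shape.

**En-face** (flat-mounted) strips have only two edges; the brightfield
detector runs with the inner-edge search disabled and the record carries
only a width. Two reporting conventions are offered by
`equivalent_diameter()`: the measured width unchanged (default, the
conservative choice since it makes no geometric assumption) or width/pi,
which reads the strip width as the unrolled circumference of the intact
vessel. An `invert` flag flips the profile sign before dispatch for
nonstandard contrast.

### Qualification thresholds

Three thresholds decide whether a derivative peak is an edge, all of them
*relative* so that one default works across 8- and 16-bit inputs and
detections are invariant to multiplying the image by a positive constant:

* `k` (default 3): a peak's prominence must exceed `k` times the robust
  (MAD-based) SD of `dF/dx` -- the noise floor of the derivative;
* `rel_prominence` (default 0.25): it must also reach this fraction of the
  strongest same-sign peak's prominence. Without this second test an
  isolated noise spike occasionally clears the MAD floor and, being
  leftmost or rightmost, would be elected an outer edge; tying candidates
  to the strongest genuine edge removes that failure mode while remaining
  scale-invariant;
* `cnr_min` (default 6): the smoothed profile's dynamic range must exceed
  `cnr_min` times a robust noise estimate taken from the raw first
  differences (`mad(diff(F))/sqrt(2)`). This contrast-to-noise gate is what
  makes a profile with no vessel in it -- e.g. a frame of pure noise --
  fail cleanly instead of reporting a spurious full-width vessel:
  purely relative peak thresholds always find *some* "edges" in noise, and
  those spurious detections cluster tightly enough that no per-frame
  consistency test can reject them.

`min_separation` (default 5 px) suppresses crowded duplicate peaks;
the taller survives, ties going leftmost, so results are deterministic.

### Sub-pixel refinement

A single-sample peak is refined by the closed-form vertex of the parabola
through its three samples, clamped to half a sample either side. A peak
with a *flat top* -- a plateau of tied samples, which is exactly what
box smoothing produces at an ideal step edge -- is refined to the plateau
centroid instead; ties are detected with a relative tolerance (1e-9 of the
signal magnitude) so floating-point dust does not split a plateau. On an
ideal symmetric step edge the centroid rule recovers the true
mid-transition exactly; the parabolic rule alone would be biased by up to
1 px because it cannot see past the plateau.

## From profiles to diameter records

ROI track lines sample `n_scanlines` (default 10) evenly spaced parallel
profiles and detect edges on each; segment lines average their
`2 * half_width + 1` (default 5) parallel offset profiles into a single
profile first, since a hand-drawn line is usually placed where averaging is
safe. Per-profile ODs are screened by a robust rule -- discard profiles
deviating from the per-line median OD by more than `3 * MAD` -- which is
what lets an ROI straddle a side-branch or adherent tissue without
corrupting the measurement. The MAD threshold carries a floor of 1e-6 px so
that noise-free, numerically identical profiles (MAD exactly 0) are not
discarded over floating-point dust. Survivors are aggregated by median; a
record is `tracked` when at least half of the attempted profiles survive.
Wall thickness is the median over profiles of the mean of the left and
right per-side widths; on a symmetric vessel this equals `(OD - ID) / 2`.

Across frames a temporal filter guards against transient tracking
failures: a tracked value deviating from the rolling median of the previous
`k_frames` (default 5) accepted values by more than `max_jump_fraction`
(default 0.25) of that median -- or a failed detection -- is replaced by
the last accepted value with status `held`. Held and failed records are
exported with their status so downstream analyses can exclude them. The
defaults are declared choices: 25% of a resistance-artery diameter is well
beyond any physiological single-frame change at ordinary frame rates,
while a 5-frame memory keeps the filter responsive to genuine
constrictions.

## The vessel phantom

The phantom renders straight tubes, three-arm (Y) branched vessels and
flat two-edged strips in any of the four modality appearances, at any axis
angle, with per-frame diameter tracks. Wall boundaries are drawn with a
1-px anti-aliasing ramp centred on the true edge *before* Gaussian PSF
blur, so the steepest intensity point stays at the exact analytic edge
position and sub-pixel accuracy claims are testable; rendering guards
against walls thinner than 2 px, which would be unresolvable. Noise is
seeded per frame as `seed + frame_index`, making stacks reproducible
frame-wise and whole pipelines reproducible end to end.

What the phantom emulates: the intensity structure of the four
preparations (bright/dark background, wall bands, lumen), optical blur,
additive Gaussian sensor noise, branched geometry, drug responses
(exponential relaxation toward a target with time constant `tau_s`) and
passive/active pressure-diameter behaviour. What it does not emulate:
B-mode speckle, uneven illumination, focus drift, wall-structure texture,
bending or out-of-plane motion of the vessel. Passing tests on phantoms
therefore demonstrate the correctness and precision of the measurement
chain, not robustness to every artefact of real recordings.

The pressure-diameter fixture is `D_p(P) = D0 (1 - a e^{-P/Pc})` for the
passive curve, minus an active myogenic-tone term that is exactly zero at
or below a threshold pressure (default 60 mmHg), rises as a cubic
smoothstep and saturates at `tone_max` by `P_sat`. These are test
fixtures with physiologically plausible shapes, not fitted physiological
models; the defaults (`D0` 200 um, `a` 0.5, `Pc` 40 mmHg, `tone_max` 40
um, threshold 60 mmHg, `P_sat` 140 mmHg) describe a generic resistance
artery that develops tone above 60 mmHg.

## The simulated pressure servo

Automated protocols step pressure from `start` to `stop` in increments of
`step`, always terminating exactly at `stop` (a non-dividing final step is
flagged partial), holding each level for `hold` seconds (default 120 s, a
typical myogenic equilibration time; the hold length is configurable
because no single value suits all vessels). The servo delivers pressure as
an exact discrete first-order relaxation toward the active setpoint --
`P_{k+1} = sp + (P_k - sp) e^{-dt/tau}` -- so closed-form checks hold to
machine precision; an optional sinusoidal oscillation (amplitude in mmHg,
rate up to 400 min^-1, the murine heart rate) rides on the setpoint to
mimic pulsatile pressure. Level transitions land on exact frame boundaries
and each is logged as a "pressure set" event in the result table.

## Numerical and I/O choices

* Bilinear interpolation for profile sampling: matches the sub-pixel
  requirement; bicubic adds cost without a testable benefit at these blur
  levels.
* TIFF I/O preserves raw integer values; on writing, integer levels are
  offset by half a code before the writer's truncation so every level
  round-trips exactly. RGB pages (e.g. ultrasound video exports) collapse
  to Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B) at load time.
* CSV export (RFC 4180, '.' decimal, UTF-8) writes absent measurements as
  empty fields, never zeros. The exact column layout is documented in the
  README and is covered by a round-trip test at 1e-6.
* All randomness flows from a single session seed; analysis of fixed input
  involves no randomness at all.

## Problem sizes used by the test-suite

The suite exercises phantoms of 50-400 px OD in frames up to 480 px wide,
20-frame constancy and hold scenarios, a 150-frame branched stack for the
independence check, 1000 randomized profiles for the invariance properties,
1000 random signals against a brute-force peak oracle, and 100-trial
detection-limit simulations at 0.345 um/px with noise at 5% of the
dynamic range. These sizes were chosen to estimate each property stably
(e.g. 150 frames put the null spread of a residual cross-correlation near
0.08, well below the 0.2 acceptance bound) while keeping the default test
run fast.

## Known limitations

* The detector assumes the profile spans the whole vessel with background
  visible on both sides; lines clipped inside the vessel fail (by design).
* Brightfield inner-edge pairing takes the strongest opposite-sign peak in
  each half-vessel; unusual wall structure (e.g. strongly layered media)
  could select an interior feature. The per-side positions are retained in
  the records for inspection.
* The temporal filter carries values forward indefinitely while detections
  keep failing; a long failure run is visible only through the `held`
  status counts.
* Ultrasound frames are treated as generic bright-band images; ECG gating
  and speckle tracking are out of scope.
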