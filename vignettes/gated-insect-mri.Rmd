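---
title: "Camera-gated MRI of a behaving insect: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-gated MRI of a behaving insect: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocogate)
```

## The problem

MRI acquires its data sequentially, one phase-encode (PE) line of k-space
per excitation. When the subject moves between excitations, the acquired
lines describe inconsistent object states and the reconstruction shows
ghosting along the phase-encode direction. For a live insect walking on a
spherical treadmill inside a high-field magnet, the dominant in-plane
disturbance is semi-periodic gross motion of the abdomen; the head and
thorax stay essentially still because the body is tethered.

One practical remedy is prospective gating, as used for respiratory
triggering in clinical MRI: an external sensor watches the subject, and
each excitation is released only when the monitored state matches a
reference. Here the sensor is a video camera and a markerless
computer-vision tracker; the monitored state is the image position of a
single keypoint on the posterior abdomen.

`mocogate` is a fully in-silico closed loop of that system. A segmented
digital insect phantom moves; a simulated camera films it; a Lucas–Kanade
tracker follows the keypoint; a gating controller compares the tracked
position with a reference pose and — subject to the modeled trigger
latency — releases RARE shots; a Cartesian k-space simulator samples the
moving phantom at each shot's fire time; an FFT reconstruction and a set
of metrics quantify the artifact level. Every stochastic element is
seeded, so whole experiments are reproducible from one master seed.

## Digital phantom and motion model

The phantom is a set of intensity-weighted ellipses (head, thorax,
abdomen, plus an internal gut-like feature) in a 30 mm body frame,
rasterized with supersampled anti-aliasing. The abdomen — and any
internal feature riding on it — is the moving part; head and thorax are
static. A frame under a given pose is composed by warping the moving
layer with an inverse-mapped bilinear interpolation (out-of-frame samples
read zero), which makes a whole-pixel translation exactly equal to an
integer array shift, a property the tests exploit.

Poses are in-plane rigid transforms about the thorax–abdomen pivot:
positive angles rotate +x toward +y in image coordinates (x = column,
rightward; y = row, downward; positions are 0-based pixel centers).

The abdominal waveform is a raised-cosine flexion pulse per cycle:
each cycle starts with a rest ("dwell") window covering a configurable
fraction of the cycle, then flexes to the peak and returns. This matches
the three-phase picture of abdominal motion — rest, flexed, rest — while
staying smooth and band-limited. Semi-periodicity is modeled as per-cycle
Gaussian jitter of the period, drawn once per cycle from a seeded stream
and truncated below at 0.2 × the base period so periods stay positive.

Defaults (all configurable):

| parameter | default | rationale |
|---|---|---|
| angular amplitude | 12° | beetle-scale abdominal flexion, ~2 mm keypoint excursion |
| translation amplitude | (0.2, 0.4) mm | small in-plane drift accompanying flexion |
| base period | 2 s | slow walking-bout rhythm |
| period jitter sd | 0.25 s | visibly irregular ("semi-periodic") cycling |
| dwell fraction | 0.35 | clear rest windows for the gate to use |
| camera frame rate | 30 Hz | the camera's maximum rate |
| camera noise sd | 0.01 | mild sensor noise relative to unit intensities |

The generator emulates: piecewise-rigid in-plane motion, rest/flexion
alternation with irregular timing, sensor noise, and exact ground-truth
keypoint positions. It deliberately does not emulate: out-of-plane or
leg/head motion, non-rigid abdomen deformation, cuticle texture,
illumination changes, or any photometric camera model. Tests that pass
on this phantom therefore demonstrate the correctness and closed-loop
behavior of the algorithms, not their robustness to appearance changes
in real video.

## Markerless tracking

Tracking solves the optical-flow constraint equation: writing the
brightness-constancy assumption `I(x, y, t) = I(x+δx, y+δy, t+δt)` to
first order gives `Ix·u + Iy·v + It = 0` per pixel. Assuming the flow
`(u, v)` is constant over a window around the keypoint yields the
over-determined system `A v = b`, with one row `(Ix, Iy)` per window
pixel and `b = −It`; the Lucas–Kanade solution is the pseudoinverse
`v = (AᵀA)⁻¹Aᵀb`.

Numerical choices:

* **Gradients.** Central differences in the interior, plain one-sided
  differences at borders. Spatial gradients are taken from the *moving*
  frame, sampled at the warped window position each iteration
  (forward-additive scheme). This makes a feature that disappears from
  the new frame report as aperture-undefined instead of being solved
  against stale structure.
* **Iterative warping.** The single linear solve is first-order, so the
  window on the second frame is re-sampled at the current displacement
  estimate and the solve repeated (default: max 10 iterations, 0.01 px
  tolerance). A 2-level image pyramid (2×2 block averaging) extends the
  capture range to several pixels per frame.
* **Conditioning.** The solve is refused when the smallest eigenvalue of
  `AᵀA` falls below `1e-4 ×` the window pixel count — a scale-aware guard
  against the aperture problem (edge-only or uniform windows). The
  15×15 default window at the abdomen tip sits on a curved boundary,
  which provides gradient diversity in both axes.
* **Losses.** A lost point is frozen, never extrapolated — for gating, a
  closed gate is the safe failure mode. Re-acquisition tracks from the
  last successfully tracked frame rather than from the lost one.

## Gating controller

The controller is a discrete-event loop on the camera clock. Per frame:
track the keypoint; if tracking is lost the gate is closed; otherwise the
gate is open iff the Euclidean distance to the reference position is
within the tolerance radius (an axis-wise mode exists but is off by
default). When the gate is open, the engine idle, and shots remain, a
trigger fires: the shot is acquired from the phantom state frozen at
`detect_time + latency`, which may fall between camera frames. The
end-to-end latency (camera frame grab through TTL pulse) defaults to
43 ms. One trigger releases exactly one shot — one excitation and its
echo train — mirroring clinical respiratory triggering; after a shot the
controller is refractory for one TR (the engine is busy and TR is the
minimum excitation spacing). The reference position defaults to the
tracked position in the first frame, i.e. the operator defines the
reference pose at setup time.

A point worth documenting because it shaped the test scenarios: for slow
motion whose rest windows are longer than the system latency, gating is
nearly latency-insensitive — a trigger detected at rest still fires at
rest, which is exactly why respiratory-style triggering tolerates
moderate delays. Latency degrades image quality only when the motion
timescale becomes comparable to the delay. The package's "fast motion"
study condition is therefore continuous 5 Hz abdominal pumping with no
dwell, where 43 ms is about a fifth of the cycle and delayed shots land
visibly displaced; under that condition gated image error increases
reliably when the latency is raised from 0 to 43 ms. With slower
waveforms the effect can even invert (a delayed trigger detected on the
incoming transit lands closer to rest), which is a phasing artifact of
smooth periodic motion, not a failure of the mechanism.

## k-space simulation

The acquisition model is inter-scan motion: the object is frozen during
each echo train (echo spacing is milliseconds; the modeled motion is
negligible at that scale) and moves only between shots. Each shot
evaluates the phantom at its fire time, takes the 2D DFT (DC-centered,
fftshift convention; PE lines are matrix rows), and keeps the shot's PE
lines. Reconstruction is the magnitude of the inverse DFT with
unacquired lines zero-filled.

Sequence arithmetic follows the RARE structure: one average needs
`floor(n_pe / rare_factor)` shots of one TR each, so
`scan_time = floor(n_pe / rare_factor) × TR × n_averages`; remainder
lines are never acquired. In-plane resolution is `FOV / n`, reported as
an integer in microns with round-half-to-even. The default PE ordering
is linear-interleaved (shot *s* acquires lines `s, s+S, s+2S, …` with
`S` the shot count); a sequential block ordering is available.

Not modeled, deliberately: relaxation weighting (T₁/T₂, echo-train
decay), slice profiles, B₀/B₁ inhomogeneity, susceptibility, gradient
nonidealities, and intra-echo-train motion. The last one matters for
RARE factors > 1 — freezing the object per shot idealizes exactly the
regime that longer echo trains make motion-sensitive — so the default
demo uses RARE factor 1, where the inter-scan model is exact.

## Metrics

Tracking accuracy is quantified as per-frame Euclidean distances between
detections and annotations matched on frame index, summarized as mean ±
sample standard deviation (n−1; the convention is configurable in
principle and documented so users can switch to the population form) in
both pixels and microns. The default pixel pitch for unit conversion is
44.6 µm/px, the ratio implied by reporting a 2.04 px error as 91 µm;
lost frames are excluded and counted. Image quality is quantified as
RMSE against a motion-free reference, a ghost-to-signal ratio
(mean |background| / mean |signal| over disjoint ROIs), and 1D intensity
profiles through the reconstruction.

## Study sizes and determinism

The default demo scenario uses a 128×128 acquisition matrix over a 30 mm
FOV (234 µm in-plane), TR 250 ms, RARE factor 1, and a 128×128 camera at
30 Hz — sizes chosen so that a full gated session (typically 1,500–2,000
camera frames and 128 shots) runs in seconds and a 20-seed study in
minutes, while still producing the classic PE-ghosting phenomenology.
The test suite runs the efficacy comparison over 20 seeds, the tolerance
sweep {∞, 8, 4, 2, 1} px over 4 seeds, and the latency comparison over
4 seeds. All randomness (cycle jitter, camera noise, measurement noise)
flows from per-subsystem seeds expanded deterministically from one
master seed, so every figure and table is bit-reproducible.

## Known limitations

* Translation-only flow model: strong rotation of the abdomen within the
  window biases the tracker; at the default amplitudes the residual is a
  fraction of a pixel, but violent flexion (tens of degrees per frame at
  coarse resolution) can lose the point.
* The gate compares positions in camera pixels; no camera–scanner
  cross-calibration is modeled (none is needed, since the reference is
  defined in the same image coordinates as the detections).
* Proton-density-only contrast; artifact levels are therefore relative,
  not absolute predictions of scanner SNR.
* Rigid, in-plane, single-joint motion only.
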