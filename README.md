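# mocogate

Closed-loop in-silico testbed for **camera-gated, motion-compensated MRI
of a behaving insect**.

Imaging a live, walking insect in a high-field magnet fails in a
characteristic way: MRI fills k-space one phase-encode line per
excitation, and semi-periodic flexion of the abdomen between excitations
makes the lines mutually inconsistent, producing ghosting along the
phase-encode direction. A practical countermeasure — analogous to
respiratory triggering in clinical MRI — is *prospective gating*: watch
the animal with a camera, track a body keypoint without markers, and
release each excitation only while the keypoint sits within a tolerance
radius of a reference pose.

`mocogate` simulates that entire loop so the method can be studied,
stress-tested and benchmarked on a desk:

* **Digital phantom + motion** — a segmented elliptical insect (static
  head/thorax, moving abdomen) driven by a raised-cosine flexion pulse
  with per-cycle period jitter and configurable rest ("dwell") windows;
  rendered as seeded camera video with exact ground-truth keypoint
  positions.
* **Markerless tracking** — sparse Lucas–Kanade optical flow built from
  the constraint equation up: windowed gradients, normal-equation /
  pseudoinverse solve `v = (AᵀA)⁻¹Aᵀb`, minimum-eigenvalue aperture
  guard, iterative warping, 2-level pyramid.
* **Prospective gating** — a discrete-event trigger controller with
  Euclidean gate, 43 ms end-to-end latency model, one shot per trigger,
  TR-refractory timing, and full gate/event logs.
* **k-space simulation** — Cartesian RARE acquisition under the
  inter-scan motion model (object frozen per shot at its fire time),
  FFT reconstruction, and the protocol calculators
  `scan_time = floor(n_pe / rare_factor) · TR · averages` and
  `resolution = FOV / n`.
* **Metrics** — Euclidean tracking-error benchmark (mean ± sd, px and
  µm), RMSE vs a motion-free reference, ghost-to-signal ratios, line
  profiles.

## Worked example

```r
library(mocogate)

# sequence arithmetic of a sagittal whole-body protocol
seqp <- sequence_params(256, 256, fov_mm = 30, tr_ms = 1000, rare_factor = 1)
scan_time(seqp)                        # 256   (seconds)
in_plane_resolution(30, 256)$reported_um   # 117 (microns)

# the full closed loop on the default 128x128 moving-phantom scenario
res <- run_closed_loop(default_run_config(master_seed = 3))
res$gate_log
#> <gate_log> 128/128 shots in 61.74 s (complete)
rmse(res$ungated, res$reference)       # 0.06582547
rmse(res$gated,   res$reference)       # 0.02277743
```

The gated acquisition waits for the abdomen's rest windows (hence the
61.7 s session instead of the 32 s ungated scan) and cuts the artifact
RMSE to roughly a third of the ungated value; tightening the gate
tolerance lowers it further, at the price of longer waits.

The tracker itself:

```r
cam <- render_phantom(default_insect_phantom(), grid = 128)
sq  <- generate_sequence(motion_model(rng_seed = 5), cam,
                         duration = 4, noise_sd = 0.01, seed = 2)
tr  <- track_sequence(sq$frames, c(sq$truth$x[1], sq$truth$y[1]))
euclidean_errors(tr, sq$truth, pixel_pitch_um = cam$pixel_pitch_um)
#> <tracking_error_report> 121 frames (0 excluded): 0.75 +/- 0.85 px (176 +/- 198 um)
```

A command-line wrapper with subcommands `phantom`, `track`, `acquire`,
`benchmark`, `report` lives in `inst/cli/mocogate`.

## Scope

The simulation models rigid in-plane abdominal motion and
proton-density contrast only; relaxation weighting, out-of-plane motion,
field inhomogeneity and camera photometrics are out of scope. See the
methods vignette (`vignettes/gated-insect-mri.Rmd`) for the models,
defaults, design decisions and limitations.
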