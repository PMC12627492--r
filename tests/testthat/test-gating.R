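test_that("gate decisions match a brute-force distance comparison", {
  cfg <- gating_config(reference_position = c(10, 20), tolerance_px = 0)
  expect_true(check_gate(c(10, 20), cfg))   # boundary inclusive
  cfg5 <- gating_config(c(0, 0), tolerance_px = 4.99)
  expect_false(check_gate(c(3, 4), cfg5))   # distance 5 > 4.99
  set.seed(42)
  ref <- c(4, -3)
  cfgr <- gating_config(ref, tolerance_px = 2.5)
  for (i in 1:1000) {
    p <- ref + runif(2, -4, 4)
    expect_identical(check_gate(p, cfgr),
                     sqrt((p[1] - ref[1])^2 + (p[2] - ref[2])^2) <= 2.5)
  }
})

test_that("triggers fire exactly one latency after detection", {
  cfg0 <- gating_config(c(0, 0), 1, latency_s = 0)
  expect_identical(emit_trigger(2.5, c(0, 0), cfg0, 0)$fire_time, 2.5)
  cfg <- gating_config(c(0, 0), 1, latency_s = 0.043)
  ev <- emit_trigger(1.000, c(0.1, 0), cfg, 3)
  expect_identical(ev$fire_time, 1.043)
  expect_identical(ev$shot_index, 3L)
  # firing during the refractory period is a controller bug
  expect_error(emit_trigger(1.01, c(0, 0), cfg, 4, last_fire_time = 1.0,
                            refractory_s = 0.25), "refractory")
})

test_that("latency budget sums its segments", {
  expect_identical(latency_budget(numeric(0)), 0)
  segs <- c(camera_frame = 0.0333, usb_cable = 0.0012, optical_flow = 0.006,
            serial_link = 0.0019, ttl_out = 0.0006)
  expect_equal(latency_budget(segs), 0.043, tolerance = 1e-12)
  set.seed(8)
  v <- runif(7)
  expect_identical(latency_budget(v), sum(v))
  expect_error(latency_budget(c(0.1, -0.01)), "non-negative")
})

# A stationary-keypoint session on a static scene: every frame tracks
# perfectly, so trigger timing is governed purely by the discrete-event
# rules (frame quantization, latency, refractory).
stationary_session <- function(n_pe = 16, tr_ms = 100, latency = 0.043,
                               frame_rate = 30, tolerance = 3) {
  r <- small_scene(48)
  still <- motion_model(angular_amplitude = 0, translation_amplitude = c(0, 0))
  kp <- render_frame(r, rigid_transform2d())$keypoint_px
  seqp <- sequence_params(48, 48, 30, tr_ms = tr_ms, rare_factor = 3L)
  cfg <- gating_config(kp, tolerance, latency_s = latency, timeout_s = 60)
  stream <- camera_stream(r, still, frame_rate = frame_rate, noise_sd = 0,
                          seed = 1)
  engine <- make_acquisition_engine(r, still)
  list(run = run_gated_session(stream, tracker_params(), cfg, engine, seqp),
       seq = seqp, cfg = cfg, frame_rate = frame_rate)
}

test_that("stationary keypoint: cadence matches a discrete-event hand simulation", {
  s <- stationary_session()
  run <- s$run
  n_shots <- length(pe_schedule(s$seq))
  expect_identical(run$gate_log$shots_completed, n_shots)
  expect_true(run$gate_log$complete)
  # independent hand simulation over the frame clock
  dt <- 1 / s$frame_rate
  tr_s <- s$seq$tr_ms / 1000
  fires <- numeric(0)
  next_ok <- -Inf
  k <- 0
  while (length(fires) < n_shots) {
    t_k <- k * dt
    if (t_k >= next_ok) {
      fires <- c(fires, t_k + s$cfg$latency_s)
      next_ok <- t_k + s$cfg$latency_s + tr_s
    }
    k <- k + 1
  }
  expect_equal(run$gate_log$events$fire_t, fires, tolerance = 1e-12)
  expect_equal(run$gate_log$duration_s, fires[n_shots], tolerance = 1e-12)
})

test_that("infinite tolerance behaves like the always-open stationary gate", {
  r <- small_scene(48)
  m <- motion_model(angular_amplitude = 6, base_period = 1,
                    period_jitter_sd = 0.1, rng_seed = 3)
  kp <- render_frame(r, rigid_transform2d())$keypoint_px
  seqp <- sequence_params(48, 48, 30, tr_ms = 120, rare_factor = 3L)
  engine <- make_acquisition_engine(r, m)
  mk <- function(tol) {
    cfg <- gating_config(kp, tol, latency_s = 0.01, timeout_s = 60)
    stream <- camera_stream(r, m, noise_sd = 0, seed = 2)
    run_gated_session(stream, tracker_params(), cfg, engine, seqp)
  }
  inf_run <- mk(Inf)
  still <- stationary_session(tr_ms = 120, latency = 0.01)
  expect_true(inf_run$gate_log$complete)
  # same trigger cadence as the stationary session (gate always open)
  expect_equal(inf_run$gate_log$events$detect_t,
               still$run$gate_log$events$detect_t, tolerance = 1e-12)
})

test_that("a keypoint never within tolerance yields a timed-out empty k-space", {
  r <- small_scene(48)
  still <- motion_model(angular_amplitude = 0, translation_amplitude = c(0, 0))
  seqp <- sequence_params(48, 48, 30, tr_ms = 100, rare_factor = 3L)
  # reference far away from the actual keypoint
  cfg <- gating_config(c(5, 5), tolerance_px = 0.5, latency_s = 0,
                       timeout_s = 2)
  stream <- camera_stream(r, still, noise_sd = 0, seed = 1)
  trk <- tracker_params()
  trk$initial_point <- render_frame(r, rigid_transform2d())$keypoint_px
  run <- run_gated_session(stream, trk, cfg,
                           make_acquisition_engine(r, still), seqp)
  expect_identical(run$gate_log$shots_completed, 0L)
  expect_false(run$kspace$complete)
  expect_true(all(run$kspace$samples == 0))
  expect_error(run_gated_session(function(k) NULL, tracker_params(), cfg,
                                 make_acquisition_engine(r, still), seqp),
               "zero frames")
})

test_that("conservation and latency exactness hold across a gated session", {
  r <- small_scene(48)
  m <- motion_model(angular_amplitude = 8, base_period = 1,
                    period_jitter_sd = 0.1, rng_seed = 9)
  kp <- render_frame(r, rigid_transform2d())$keypoint_px
  seqp <- sequence_params(48, 48, 30, tr_ms = 150, rare_factor = 2L)
  cfg <- gating_config(kp, 2, latency_s = 0.043, timeout_s = 120)
  stream <- camera_stream(r, m, noise_sd = 0.005, seed = 5)
  run <- run_gated_session(stream, tracker_params(), cfg,
                           make_acquisition_engine(r, m), seqp)
  ev <- run$gate_log$events
  # one trigger per acquired shot; no line acquired without a trigger
  expect_identical(nrow(ev), run$gate_log$shots_completed)
  expect_setequal(unique(run$kspace$line_shot[run$kspace$acquired]), ev$shot)
  expect_true(all(is.na(run$kspace$line_time_s[!run$kspace$acquired])))
  # fire - detect equals the configured latency exactly
  expect_true(all(abs(ev$fire_t - ev$detect_t - 0.043) < 1e-12))
  # events ordered by fire time
  expect_true(all(diff(ev$fire_t) > 0))
})

test_that("enlarging the tolerance never slows the session down", {
  r <- small_scene(48)
  m <- motion_model(angular_amplitude = 8, base_period = 0.8,
                    period_jitter_sd = 0.08, rng_seed = 4)
  kp <- render_frame(r, rigid_transform2d())$keypoint_px
  seqp <- sequence_params(48, 48, 30, tr_ms = 100, rare_factor = 3L)
  engine <- make_acquisition_engine(r, m)
  durs <- vapply(c(1, 4, Inf), function(tol) {
    cfg <- gating_config(kp, tol, latency_s = 0.02, timeout_s = 90)
    stream <- camera_stream(r, m, noise_sd = 0, seed = 2)
    run_gated_session(stream, tracker_params(), cfg, engine, seqp)$gate_log$duration_s
  }, 0)
  expect_true(all(diff(durs) <= 1e-12))
})

test_that("acquired shots respect the residual-motion displacement bound", {
  r <- small_scene(64)
  spec <- default_insect_phantom()
  m <- motion_model(angular_amplitude = 8, base_period = 0.8,
                    period_jitter_sd = 0.05, rng_seed = 12)
  kp <- render_frame(r, rigid_transform2d())$keypoint_px
  seqp <- sequence_params(64, 64, 30, tr_ms = 120, rare_factor = 2L)
  cfg <- gating_config(kp, 1.5, latency_s = 0.043, timeout_s = 120)
  stream <- camera_stream(r, m, noise_sd = 0, seed = 3)
  run <- run_gated_session(stream, tracker_params(), cfg,
                           make_acquisition_engine(r, m), seqp)
  expect_true(run$gate_log$complete)
  kp_at <- function(t) {
    mm <- apply_transform(eval_motion(m, t), spec$keypoint, spec$pivot)
    mm / r$delta_mm - 0.5
  }
  # numeric bound on the keypoint speed over the session
  ts <- seq(0, max(run$gate_log$events$fire_t), by = 0.002)
  ps <- t(vapply(ts, kp_at, c(0, 0)))
  vmax <- max(sqrt(rowSums(diff(ps)^2))) / 0.002
  # true displacement from reference at each fire time, tracking noise-free
  for (i in seq_len(nrow(run$gate_log$events))) {
    d <- sqrt(sum((kp_at(run$gate_log$events$fire_t[i]) - kp)^2))
    # tolerance + motion during the latency window + tracker error margin
    expect_lt(d, 1.5 + vmax * 0.043 + 0.35)
  }
})
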