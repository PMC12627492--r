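test_that("phantom rasterization: empty scene, full-intensity interior, FOV guard", {
  empty <- phantom_spec(list(), pivot = c(15, 15), keypoint = c(20, 15))
  r <- render_phantom(empty, grid = 32)
  expect_true(all(r$image == 0))

  one <- phantom_spec(list(list(label = "abdomen", center = c(15, 15),
                                semi_axes = c(8, 6), intensity = 1)),
                      pivot = c(15, 15), keypoint = c(20, 15))
  r1 <- render_phantom(one, grid = 64)
  # pixels well inside the ellipse are exactly 1
  inside <- r1$masks$abdomen
  core <- matrix(FALSE, 64, 64); core[28:36, 28:36] <- TRUE
  expect_true(all(r1$image[core] == 1))
  expect_true(all(inside[core]))

  off <- phantom_spec(list(list(label = "head", center = c(29, 15),
                                semi_axes = c(3, 3), intensity = 0.5)),
                      pivot = c(15, 15), keypoint = c(20, 15))
  expect_error(render_phantom(off, grid = 32), "head")
  expect_error(render_phantom(empty, grid = 8), "at least 16")
  expect_error(phantom_spec(list(list(label = "head", center = c(5, 5),
                                      semi_axes = c(1, 1), intensity = 1.2)),
                            c(5, 5), c(5, 5)), "intensity")
})

test_that("rendering is linear in segment intensities (superposition)", {
  seg_a <- list(label = "head", center = c(8, 10), semi_axes = c(3, 2),
                intensity = 0.4)
  seg_b <- list(label = "abdomen", center = c(20, 18), semi_axes = c(5, 4),
                intensity = 0.9)
  mk <- function(segs) render_phantom(
    phantom_spec(segs, pivot = c(14, 14), keypoint = c(22, 18)), grid = 48)
  both <- mk(list(seg_a, seg_b))
  a <- mk(list(seg_a)); b <- mk(list(seg_b))
  expect_equal(both$image, a$image + b$image, tolerance = 1e-14)
})

test_that("rigid transforms: identity, pivot fixed point, handedness, inverse", {
  p <- c(3.2, -1.7)
  expect_equal(apply_transform(rigid_transform2d(), p, c(0, 0)), p)
  # the pivot is the fixed point of a pure rotation
  expect_equal(apply_transform(rigid_transform2d(1.234), c(5, 7), c(5, 7)),
               c(5, 7))
  # positive angle turns +x toward +y
  expect_equal(apply_transform(rigid_transform2d(pi / 2), c(1, 0), c(0, 0)),
               c(0, 1), tolerance = 1e-12)
  # composing with the inverse is the identity to 1e-12
  tf <- rigid_transform2d(0.37, c(1.2, -0.8))
  q <- apply_transform(tf, p, c(2, 3))
  expect_equal(apply_transform(invert_transform(tf), q, c(2, 3)), p,
               tolerance = 1e-12)
})

test_that("motion model: rest cases, dwell window, seeded peak amplitude", {
  still <- motion_model(angular_amplitude = 0, translation_amplitude = c(0, 0),
                        rng_seed = 3)
  for (t in c(0, 0.7, 3.3, 11))
    expect_true(is_identity_transform(eval_motion(still, t)))

  m <- motion_model(angular_amplitude = 10, base_period = 2,
                    period_jitter_sd = 0.3, dwell_fraction = 0.4,
                    translation_amplitude = c(0.5, 0.2), rng_seed = 11)
  # re-simulate the jittered cycle boundaries from the same seed
  # (independent of motion_cycles' internals)
  set.seed(11L)
  z <- rnorm(40, 0, 0.3)
  periods <- pmax(0.2 * 2, 2 + z)
  starts <- cumsum(c(0, periods[-40]))
  # inside the dwell window of cycle 3 the pose is exactly the rest pose
  t_dwell <- starts[3] + 0.5 * 0.4 * periods[3]
  expect_true(is_identity_transform(eval_motion(m, t_dwell)))
  # at the cycle peak the angle equals the amplitude
  t_peak <- starts[3] + 0.4 * periods[3] + 0.5 * 0.6 * periods[3]
  tf <- eval_motion(m, t_peak)
  expect_equal(tf$rotation_angle, 10 * pi / 180, tolerance = 1e-12)
  expect_equal(tf$translation, c(0.5, 0.2), tolerance = 1e-12)
  # boundaries agree with the package's own table
  cyc <- motion_cycles(m, 50)
  expect_equal(cyc$start, starts[starts <= 50], tolerance = 1e-12)
})

test_that("dwell fraction is conserved over many cycles", {
  m <- motion_model(angular_amplitude = 8, base_period = 1,
                    period_jitter_sd = 0.15, dwell_fraction = 0.3,
                    rng_seed = 21)
  ts <- seq(0, 40, by = 0.013)  # > 30 jittered cycles, off-grid sampling
  idle <- vapply(ts, function(t) is_identity_transform(eval_motion(m, t)),
                 TRUE)
  p_hat <- mean(idle)
  se <- sqrt(0.3 * 0.7 / length(ts))
  # binomial error bound is loose here (samples within a cycle are
  # correlated); allow the cycle-level fluctuation too
  expect_lt(abs(p_hat - 0.3), 5 * se + 0.03)
})

test_that("frame rendering: identity pose, integer-pixel shift oracle, determinism", {
  r <- small_scene()
  f0 <- render_frame(r, rigid_transform2d())
  expect_equal(f0$frame$pixels, r$image)
  expect_equal(f0$keypoint_px,
               default_insect_phantom()$keypoint / r$delta_mm - 0.5)

  # pure translation by whole pixels: warped moving layer equals the
  # integer array shift of the static moving layer
  d_px <- c(3, -2)
  f1 <- render_frame(r, rigid_transform2d(0, d_px * r$delta_mm))
  shifted <- matrix(0, 64, 64)
  shifted[(1 + 0):(64 - 2) - 0, (1 + 3):64] <-
    r$moving_img[(1 - 0 + 2):64, 1:(64 - 3)]
  oracle <- r$static_img + shifted
  expect_equal(f1$frame$pixels, oracle, tolerance = 1e-12)

  # seeded noise renders are bit-identical across runs
  set.seed(9); g1 <- render_frame(r, rigid_transform2d(0.1), noise_sd = 0.01)
  set.seed(9); g2 <- render_frame(r, rigid_transform2d(0.1), noise_sd = 0.01)
  expect_identical(g1$frame$pixels, g2$frame$pixels)
})

test_that("sequence generation: frame count, timestamps, closed-form Y excursion", {
  r <- small_scene(48)
  still <- motion_model(angular_amplitude = 0, translation_amplitude = c(0, 0))
  s <- generate_sequence(still, r, frame_rate = 30, duration = 1)
  expect_length(s$frames, 31)
  expect_equal(s$truth$t, (0:30) / 30)
  expect_true(all(s$truth$x == s$truth$x[1]) && all(s$truth$y == s$truth$y[1]))

  # pure flexion, no jitter: a frame lands exactly on the waveform peak
  # (period 2, dwell 0.5 -> peak at t = 1.5), where the keypoint y-offset
  # is sin(amplitude) times its lever arm about the pivot
  A <- 9
  m <- motion_model(angular_amplitude = A, base_period = 2,
                    period_jitter_sd = 0, dwell_fraction = 0.5,
                    translation_amplitude = c(0, 0), rng_seed = 2)
  sp <- default_insect_phantom()
  sq <- generate_sequence(m, r, frame_rate = 30, duration = 2)
  lever <- sp$keypoint[1] - sp$pivot[1]
  expected_pp <- abs(sin(A * pi / 180) * lever) / r$delta_mm
  expect_equal(max(sq$truth$y) - min(sq$truth$y), expected_pp,
               tolerance = 1e-9)

  # determinism of the full stack
  s1 <- generate_sequence(m, r, duration = 0.5, noise_sd = 0.02, seed = 4)
  s2 <- generate_sequence(m, r, duration = 0.5, noise_sd = 0.02, seed = 4)
  expect_identical(lapply(s1$frames, `[[`, "pixels"),
                   lapply(s2$frames, `[[`, "pixels"))
})

test_that("stored ground truth is recoverable by cross-correlation", {
  r <- small_scene(96)
  f0 <- render_frame(r, rigid_transform2d())
  kp0 <- f0$keypoint_px
  # template patch around the rest-pose keypoint
  hw <- 6
  patch_at <- function(img, cx, cy) {
    xs <- rep(cx + (-hw:hw), each = 2 * hw + 1)
    ys <- rep(cy + (-hw:hw), times = 2 * hw + 1)
    mocogate:::bilinear_sample(img, xs, ys)
  }
  tpl <- patch_at(f0$frame$pixels, kp0[1], kp0[2])
  # mild pose change (translation plus a small flexion), noise-free
  tf <- rigid_transform2d(3 * pi / 180, c(0.6, 0.9))
  f1 <- render_frame(r, tf)
  ncc <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  # quarter-pixel search grid around the rest position
  offs <- expand.grid(dx = seq(-6, 6, by = 0.25), dy = seq(-6, 6, by = 0.25))
  scores <- mapply(function(dx, dy)
    ncc(tpl, patch_at(f1$frame$pixels, kp0[1] + dx, kp0[2] + dy)),
    offs$dx, offs$dy)
  best <- offs[which.max(scores), ]
  found <- c(kp0[1] + best$dx, kp0[2] + best$dy)
  expect_lt(sqrt(sum((found - f1$keypoint_px)^2)), 0.5)
})
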