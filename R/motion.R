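#' Semi-periodic abdominal motion model
#'
#' The abdomen rests, flexes, and returns once per cycle: each cycle
#' starts with a dwell (rest) window covering `dwell_fraction` of the
#' cycle, followed by a raised-cosine flexion pulse that peaks midway
#' through the active part and returns to rest. Semi-periodicity is
#' realized as per-cycle Gaussian jitter of the cycle period, drawn once
#' per cycle from a stream seeded by `rng_seed`, so the model is fully
#' deterministic given its seed.
#'
#' @param angular_amplitude peak flexion angle in degrees (>= 0).
#' @param base_period mean cycle period in seconds (> 0).
#' @param period_jitter_sd per-cycle period jitter sd in seconds;
#'   jittered periods are truncated below at `0.2 * base_period`.
#' @param translation_amplitude length-2 peak translation in mm.
#' @param dwell_fraction fraction of each cycle spent at the rest pose,
#'   in `[0, 1)`.
#' @param phase_offset phase offset in radians (shifts the waveform by
#'   `phase_offset / (2 * pi)` of one base period).
#' @param rng_seed integer seed for the jitter stream.
#' @return object of class `motion_model`.
#' @export
#' @examples
#' m <- motion_model(angular_amplitude = 12, base_period = 2)
#' eval_motion(m, 0)$rotation_angle  # 0: cycles start at rest
motion_model <- function(angular_amplitude = 12,
                         base_period = 2,
                         period_jitter_sd = 0.25,
                         translation_amplitude = c(0.2, 0.4),
                         dwell_fraction = 0.35,
                         phase_offset = 0,
                         rng_seed = 1L) {
  stopifnot(base_period > 0, dwell_fraction >= 0, dwell_fraction < 1,
            angular_amplitude >= 0, period_jitter_sd >= 0,
            length(translation_amplitude) == 2,
            all(translation_amplitude >= 0))
  m <- list(angular_amplitude = angular_amplitude,
            base_period = base_period,
            period_jitter_sd = period_jitter_sd,
            translation_amplitude = as.numeric(translation_amplitude),
            dwell_fraction = dwell_fraction,
            phase_offset = phase_offset,
            rng_seed = as.integer(rng_seed))
  m$cache <- new.env(parent = emptyenv())
  structure(m, class = "motion_model")
}

#' Jittered cycle boundaries of a motion model
#'
#' Returns the cycle start times and periods covering `[0, t_max]`.
#' Period `i` is `max(0.2 * base_period, base_period + z_i)` where the
#' `z_i` are i.i.d. `Normal(0, period_jitter_sd)` draws from the model's
#' seeded stream, so any prefix of the table is reproducible.
#'
#' @param model a [motion_model()].
#' @param t_max time horizon in seconds.
#' @return data.frame with columns `start`, `period`.
#' @export
motion_cycles <- function(model, t_max) {
  n_need <- ceiling((t_max + model$base_period) /
                      (0.2 * model$base_period)) + 2L
  cache <- model$cache
  if (is.null(cache$periods) || length(cache$periods) < n_need) {
    z <- with_seed(model$rng_seed, stats::rnorm(n_need, 0, model$period_jitter_sd))
    cache$periods <- pmax(0.2 * model$base_period, model$base_period + z)
    cache$starts <- cumsum(c(0, cache$periods[-n_need]))
  }
  keep <- cache$starts <= t_max
  data.frame(start = cache$starts[keep], period = cache$periods[keep])
}

# raised-cosine waveform value in [0, 1] at time t (scalar or vector)
motion_waveform <- function(model, t) {
  t <- t + model$phase_offset / (2 * pi) * model$base_period
  t <- pmax(t, 0)
  cyc <- motion_cycles(model, max(t))
  k <- findInterval(t, cyc$start)
  tau <- t - cyc$start[k]
  P <- cyc$period[k]
  D <- model$dwell_fraction * P
  w <- numeric(length(t))
  act <- tau >= D
  s <- (tau[act] - D[act]) / (P[act] - D[act])
  w[act] <- 0.5 * (1 - cos(2 * pi * s))
  w
}

#' Evaluate the motion model at a time point
#'
#' Returns the abdomen pose at time `t` as a rigid transform about the
#' phantom pivot: zero (rest pose) during each cycle's dwell window,
#' otherwise the raised-cosine waveform scales both the flexion angle and
#' the translation.
#'
#' @param model a [motion_model()].
#' @param t time in seconds (scalar, >= 0).
#' @return a [rigid_transform2d()].
#' @export
eval_motion <- function(model, t) {
  stopifnot(length(t) == 1, t >= 0)
  w <- motion_waveform(model, t)
  rigid_transform2d(model$angular_amplitude * pi / 180 * w,
                    model$translation_amplitude * w)
}

#' Generate a camera frame sequence with ground truth
#'
#' Renders `floor(duration * frame_rate) + 1` frames at uniform spacing
#' `1 / frame_rate` starting at t = 0, with per-frame Gaussian camera
#' noise from a seeded stream, and the ground-truth keypoint trajectory
#' aligned by frame index.
#'
#' @param model a [motion_model()].
#' @param render a [render_phantom()] result (the camera's view).
#' @param frame_rate frames per second (> 0); the integrated camera's
#'   maximum rate, 30 Hz, is the default.
#' @param duration sequence length in seconds (> 0, start inclusive).
#' @param noise_sd camera noise sd (intensity units).
#' @param seed integer seed for the camera noise stream.
#' @return list with `frames` (list of `image_frame`) and `truth`
#'   (data.frame `frame`, `t`, `x`, `y` in 0-based pixels).
#' @export
generate_sequence <- function(model, render, frame_rate = 30, duration = 2,
                              noise_sd = 0, seed = 1L) {
  stopifnot(frame_rate > 0, duration > 0)
  n <- floor(duration * frame_rate) + 1L
  ts <- (seq_len(n) - 1L) / frame_rate
  frames <- vector("list", n)
  truth <- data.frame(frame = seq_len(n) - 1L, t = ts, x = NA_real_, y = NA_real_)
  with_seed(seed, {
    for (k in seq_len(n)) {
      fr <- render_frame(render, eval_motion(model, ts[k]), t = ts[k],
                         frame_index = k - 1L, noise_sd = noise_sd)
      frames[[k]] <- fr$frame
      truth$x[k] <- fr$keypoint_px[1]
      truth$y[k] <- fr$keypoint_px[2]
    }
  })
  list(frames = frames, truth = truth)
}
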