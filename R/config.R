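#' Default closed-loop run configuration
#'
#' The complete set of parameters of a closed-loop run: phantom, motion
#' model, camera, tracker, gate and sequence, plus a single master seed
#' that is deterministically expanded into per-subsystem seeds (motion
#' jitter, camera noise, measurement noise) so one number reproduces an
#' entire run.
#'
#' @param master_seed integer master seed.
#' @return named list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_run_config(master_seed = 7)
#' cfg$seeds
default_run_config <- function(master_seed = 1L) {
  seeds <- expand_seed(master_seed, c("motion", "camera", "measurement"))
  structure(list(
    master_seed = as.integer(master_seed),
    seeds = as.list(seeds),
    phantom = list(body_frame_extent = 30),
    motion = list(angular_amplitude = 12, base_period = 2,
                  period_jitter_sd = 0.25,
                  translation_amplitude = c(0.2, 0.4),
                  dwell_fraction = 0.35, phase_offset = 0),
    camera = list(grid = 128, frame_rate_hz = 30, noise_sd = 0.01),
    tracker = list(window_halfwidth = 7, max_iters = 10, conv_tol_px = 0.01,
                   pyramid_levels = 2),
    gating = list(tolerance_px = 2, latency_s = 0.043,
                  timeout_factor = 12),
    sequence = list(n_read = 128, n_pe = 128, fov_mm = 30, tr_ms = 250,
                    te_ms = 5, rare_factor = 1, n_averages = 1,
                    pe_ordering = "linear-interleaved",
                    slice_thickness_mm = 1)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' A configuration round-trips losslessly through its YAML form.
#'
#' @param config a `run_config`.
#' @param path YAML file.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_run_config(raw$master_seed %||% 1L)
  for (nm in intersect(names(raw), names(base))) {
    if (is.list(base[[nm]]) && is.list(raw[[nm]])) {
      for (k in names(raw[[nm]])) base[[nm]][[k]] <- raw[[nm]][[k]]
    } else {
      base[[nm]] <- raw[[nm]]
    }
  }
  base$seeds <- as.list(expand_seed(base$master_seed,
                                    c("motion", "camera", "measurement")))
  base
}

# Instantiate the simulation objects described by a run_config.
build_run <- function(config) {
  spec <- default_insect_phantom(config$phantom$body_frame_extent)
  model <- motion_model(
    angular_amplitude = config$motion$angular_amplitude,
    base_period = config$motion$base_period,
    period_jitter_sd = config$motion$period_jitter_sd,
    translation_amplitude = unlist(config$motion$translation_amplitude),
    dwell_fraction = config$motion$dwell_fraction,
    phase_offset = config$motion$phase_offset,
    rng_seed = config$seeds$motion)
  seqp <- do.call(sequence_params, config$sequence)
  cam <- render_phantom(spec, grid = config$camera$grid,
                        fov_mm = spec$body_frame_extent)
  mri <- render_phantom(spec, grid = c(seqp$n_pe, seqp$n_read),
                        fov_mm = seqp$fov_mm[1])
  tracker <- do.call(tracker_params, config$tracker[
    intersect(names(config$tracker), names(formals(tracker_params)))])
  list(spec = spec, model = model, seq = seqp, camera_render = cam,
       mri_render = mri, tracker = tracker)
}

#' Run the full closed-loop demo scenario
#'
#' Executes the complete pipeline described by a run configuration:
#' renders the moving phantom, streams camera frames to the
#' Lucas-Kanade tracker, gates RARE shots against the reference pose
#' (the keypoint's rest position) and reconstructs. Also produces the
#' ungated acquisition and the motion-free reference for comparison.
#'
#' @param config a [default_run_config()]-style `run_config`.
#' @param gated logical: run the gated session (else only ungated +
#'   reference).
#' @param latency_s optional override of the configured latency.
#' @param tolerance_px optional override of the configured tolerance.
#' @param conditions subset of `c("reference", "ungated")` to compute in
#'   addition to the gated session; callers comparing many gated runs
#'   against one shared reference can drop both.
#' @return list with `reference`, `ungated`, and (when `gated`) `gated`
#'   recon images, the underlying `kspace` objects, `gate_log` and
#'   tracked `trajectory`.
#' @export
run_closed_loop <- function(config = default_run_config(), gated = TRUE,
                            latency_s = NULL, tolerance_px = NULL,
                            conditions = c("reference", "ungated")) {
  rb <- build_run(config)
  out <- list()
  if ("reference" %in% conditions)
    out$reference <- reconstruct(acquire_series(rb$seq, rb$mri_render,
                                                model = NULL))
  if ("ungated" %in% conditions) {
    ungated_ks <- acquire_series(rb$seq, rb$mri_render, rb$model)
    out$ungated <- reconstruct(ungated_ks)
    out$ungated_kspace <- ungated_ks
  }
  if (gated) {
    kp0 <- render_frame(rb$camera_render, rigid_transform2d())$keypoint_px
    cfg <- gating_config(
      reference_position = kp0,
      tolerance_px = tolerance_px %||% config$gating$tolerance_px,
      latency_s = latency_s %||% config$gating$latency_s,
      timeout_s = config$gating$timeout_factor * scan_time(rb$seq))
    engine <- make_acquisition_engine(rb$mri_render, rb$model)
    stream <- camera_stream(rb$camera_render, rb$model,
                            frame_rate = config$camera$frame_rate_hz,
                            noise_sd = config$camera$noise_sd,
                            seed = config$seeds$camera)
    sess <- run_gated_session(stream, rb$tracker, cfg, engine, rb$seq)
    out$gated <- reconstruct(sess$kspace)
    out$gated_kspace <- sess$kspace
    out$gate_log <- sess$gate_log
    out$trajectory <- sess$trajectory
  }
  out
}

#' Lazy camera frame generator
#'
#' Returns a generator `function(k)` producing camera frame `k`
#' (0-based) of the moving phantom on demand, with deterministic
#' per-frame noise (each frame's noise is drawn from a stream seeded by
#' `seed + k`, so frames are identical whether generated lazily or in
#' batch order).
#'
#' @param render a [render_phantom()] camera view.
#' @param model a [motion_model()].
#' @param frame_rate frames per second.
#' @param noise_sd camera noise sd.
#' @param seed base seed of the per-frame noise streams.
#' @param max_frames generator returns `NULL` beyond this count.
#' @return function of `k`.
#' @export
camera_stream <- function(render, model, frame_rate = 30, noise_sd = 0.01,
                          seed = 1L, max_frames = Inf) {
  force(render); force(model)
  function(k) {
    if (k >= max_frames) return(NULL)
    t_k <- k / frame_rate
    with_seed((as.numeric(seed) + k) %% 2147483647, {
      render_frame(render, eval_motion(model, t_k), t = t_k,
                   frame_index = k, noise_sd = noise_sd)$frame
    })
  }
}
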