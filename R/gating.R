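#' Prospective gating configuration
#'
#' Reference pose, tolerance and timing of the trigger controller. The
#' gate is open when the tracked keypoint lies within `tolerance_px`
#' (Euclidean) of `reference_position`; a fired trigger releases exactly
#' one acquisition shot after the modeled end-to-end system latency
#' (camera frame to TTL trigger), 43 ms by default.
#'
#' @param reference_position length-2 reference keypoint (0-based px).
#' @param tolerance_px Euclidean tolerance radius in px (>= 0; may be
#'   `Inf` for an always-open gate).
#' @param latency_s end-to-end trigger latency in seconds (default 0.043).
#' @param refractory_s minimum time between trigger firings; defaults to
#'   the sequence TR when a session is run (the engine is busy for one
#'   shot and TR is the minimum shot spacing).
#' @param timeout_s maximum session length in seconds.
#' @param axis optional `"x"` or `"y"` for an axis-wise gate instead of
#'   the default Euclidean comparison.
#' @return object of class `gating_config`.
#' @export
gating_config <- function(reference_position, tolerance_px,
                          latency_s = 0.043, refractory_s = NULL,
                          timeout_s = Inf, axis = NULL) {
  stopifnot(length(reference_position) == 2, tolerance_px >= 0,
            latency_s >= 0, is.null(refractory_s) || refractory_s >= 0)
  if (!is.null(axis)) axis <- match.arg(axis, c("x", "y"))
  structure(list(reference_position = as.numeric(reference_position),
                 tolerance_px = tolerance_px, latency_s = latency_s,
                 refractory_s = refractory_s, timeout_s = timeout_s,
                 axis = axis),
            class = "gating_config")
}

#' Gate decision for a tracked position
#'
#' Open iff the Euclidean distance between `position` and the reference
#' is at most `tolerance_px` (boundary inclusive); axis-wise when the
#' config selects an axis.
#'
#' @param position length-2 tracked position (px), finite.
#' @param config a [gating_config()].
#' @return `TRUE` (open) or `FALSE` (closed).
#' @export
check_gate <- function(position, config) {
  if (!all(is.finite(position))) return(FALSE)
  d <- position - config$reference_position
  dist <- if (is.null(config$axis)) sqrt(sum(d^2))
          else abs(d[[if (config$axis == "x") 1 else 2]])
  dist <= config$tolerance_px
}

#' Fire a trigger event
#'
#' Creates the trigger released when the gate is open: the acquisition
#' fires exactly `latency_s` after detection.
#'
#' @param detect_time detection time (s).
#' @param detect_position tracked position at detection (px).
#' @param config a [gating_config()].
#' @param shot_index 0-based index of the shot this trigger releases.
#' @param last_fire_time fire time of the previous trigger (used to
#'   guard the refractory period; `-Inf` when none).
#' @param refractory_s effective refractory interval (s).
#' @return list of class `trigger_event` with `detect_time`, `fire_time`
#'   (`= detect_time + latency_s`), `detect_position`, `shot_index`.
#' @export
emit_trigger <- function(detect_time, detect_position, config, shot_index,
                         last_fire_time = -Inf, refractory_s = 0) {
  if (detect_time < last_fire_time + refractory_s)
    stop("trigger emitted during the refractory period (controller bug)")
  structure(list(detect_time = detect_time,
                 fire_time = detect_time + config$latency_s,
                 detect_position = as.numeric(detect_position),
                 shot_index = as.integer(shot_index)),
            class = "trigger_event")
}

#' Total system latency from its segments
#'
#' Sums the per-segment latencies of the trigger chain (camera frame
#' grab, cable transport, optical-flow computation, serial link, TTL).
#'
#' @param segment_latencies named numeric vector or list of
#'   `(name, seconds)` pairs; all non-negative.
#' @return total latency in seconds.
#' @export
#' @examples
#' latency_budget(c(frame = 0.0333, compute = 0.006, serial = 0.0037))
latency_budget <- function(segment_latencies) {
  v <- if (is.list(segment_latencies)) {
    vapply(segment_latencies, function(s) as.numeric(s[[length(s)]]), 0)
  } else as.numeric(segment_latencies)
  if (any(v < 0)) stop("latency segments must be non-negative")
  sum(v)
}

#' Run a prospectively gated acquisition session
#'
#' Discrete-event loop over the camera frames: each frame is tracked
#' with the Lucas-Kanade tracker; a lost track closes the gate; when the
#' gate is open, the engine idle (outside the refractory interval) and
#' shots remain, a trigger fires and the engine acquires the next
#' pending shot from the phantom state frozen at the trigger's fire
#' time (`detect + latency`, which may fall between camera frames). The
#' session ends when all shots are acquired, the frame stream ends, or
#' the timeout elapses; an incomplete k-space is returned zero-filled
#' and flagged.
#'
#' @param frames list of `image_frame`s, or a generator
#'   `function(k)` returning frame `k` (0-based) or `NULL` when
#'   exhausted.
#' @param tracker a [tracker_params()] list; element `initial_point`
#'   (px) may override the reference as the tracker's starting point.
#' @param config a [gating_config()].
#' @param engine an acquisition engine from [make_acquisition_engine()].
#' @param seq a [sequence_params()].
#' @return list with `kspace` (`kspace_data`), `gate_log` (class
#'   `gate_log`: `events` data.frame
#'   `shot,detect_t,fire_t,x,y`, `state` data.frame `frame,t,state`
#'   with state in open/closed/refractory/lost, `duration_s` = fire time
#'   of the last shot, `shots_completed`, `shots_required`, `complete`),
#'   and `trajectory` (tracked keypoint trajectory data.frame).
#' @export
run_gated_session <- function(frames, tracker, config, engine, seq) {
  shots <- pe_schedule(seq)
  if (seq$n_averages != 1L)
    stop("gated sessions support a single average")
  n_shots <- length(shots)
  refractory <- config$refractory_s %||% (seq$tr_ms / 1000)
  ks <- new_kspace(seq)
  get_frame <- if (is.function(frames)) frames else {
    function(k) if (k + 1 <= length(frames)) frames[[k + 1]] else NULL
  }
  f0 <- get_frame(0)
  if (is.null(f0)) stop("zero frames supplied")
  pos <- as.numeric(tracker$initial_point %||% config$reference_position)
  ref_frame <- f0
  events <- list()
  cap <- 1024L
  tr_t <- numeric(cap); tr_x <- numeric(cap); tr_y <- numeric(cap)
  tr_status <- character(cap); st_gate <- character(cap)
  last_fire <- -Inf
  shot_idx <- 0L
  acc <- ks$samples
  k <- 0L
  n_seen <- 0L
  frame <- f0
  repeat {
    t_k <- frame$timestamp
    if (t_k > config$timeout_s) break
    status <- "tracked"
    if (k > 0L) {
      st <- track_step(ref_frame, frame, pos, tracker)
      status <- st$status
      if (status == "tracked") {
        pos <- st$position
        ref_frame <- frame
      }
    }
    gate <- if (status == "lost") "lost"
            else if (t_k < last_fire + refractory) "refractory"
            else if (check_gate(pos, config)) "open" else "closed"
    if (gate == "open" && shot_idx < n_shots) {
      ev <- emit_trigger(t_k, pos, config, shot_idx, last_fire, refractory)
      pe <- shots[[shot_idx + 1L]]
      acc[pe + 1L, ] <- engine(ev$fire_time, pe)
      ks$line_time_s[pe + 1L] <- ev$fire_time
      ks$line_shot[pe + 1L] <- shot_idx
      ks$acquired[pe + 1L] <- TRUE
      last_fire <- ev$fire_time
      events[[length(events) + 1L]] <- ev
      shot_idx <- shot_idx + 1L
    }
    if (k + 1L > cap) {
      cap <- cap * 2L
      length(tr_t) <- cap; length(tr_x) <- cap; length(tr_y) <- cap
      length(tr_status) <- cap; length(st_gate) <- cap
    }
    tr_t[k + 1L] <- t_k; tr_x[k + 1L] <- pos[1]; tr_y[k + 1L] <- pos[2]
    tr_status[k + 1L] <- status; st_gate[k + 1L] <- gate
    n_seen <- k + 1L
    if (shot_idx >= n_shots) break
    k <- k + 1L
    frame <- get_frame(k)
    if (is.null(frame)) break
  }
  idx <- seq_len(n_seen)
  ks$samples <- acc
  ks$complete <- shot_idx >= n_shots
  ev_df <- if (length(events)) {
    data.frame(shot = vapply(events, `[[`, 0L, "shot_index"),
               detect_t = vapply(events, `[[`, 0, "detect_time"),
               fire_t = vapply(events, `[[`, 0, "fire_time"),
               x = vapply(events, function(e) e$detect_position[1], 0),
               y = vapply(events, function(e) e$detect_position[2], 0))
  } else {
    data.frame(shot = integer(), detect_t = numeric(), fire_t = numeric(),
               x = numeric(), y = numeric())
  }
  log <- structure(list(events = ev_df,
                        state = data.frame(frame = idx - 1L, t = tr_t[idx],
                                           state = st_gate[idx]),
                        duration_s = if (nrow(ev_df)) max(ev_df$fire_t) else NA_real_,
                        shots_completed = shot_idx,
                        shots_required = n_shots,
                        complete = shot_idx >= n_shots),
                   class = "gate_log")
  traj <- data.frame(frame = idx - 1L, t = tr_t[idx], x = tr_x[idx],
                     y = tr_y[idx], status = tr_status[idx])
  list(kspace = ks, gate_log = log, trajectory = traj)
}

#' @export
print.gate_log <- function(x, ...) {
  cat(sprintf("<gate_log> %d/%d shots in %.2f s (%s)\n",
              x$shots_completed, x$shots_required,
              x$duration_s %||% NA, if (x$complete) "complete" else "incomplete"))
  invisible(x)
}
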