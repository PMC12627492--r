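#' Cartesian RARE sequence parameters
#'
#' Protocol description for the simulated fast-spin-echo (RARE)
#' acquisition: matrix size, field of view, repetition/echo times, echo
#' train length (RARE factor), averaging and phase-encode ordering.
#'
#' @param n_read readout matrix size (>= 8).
#' @param n_pe number of phase-encode lines (>= 8).
#' @param fov_mm field of view in mm; scalar or length-2 (read, pe).
#' @param tr_ms repetition time in ms.
#' @param te_ms echo time in ms (bookkeeping only; relaxation is not
#'   simulated).
#' @param rare_factor echo train length, `1 <= rare_factor <= n_pe`.
#' @param n_averages number of signal averages (>= 1).
#' @param pe_ordering `"linear-interleaved"` (default) or `"sequential"`.
#' @param slice_thickness_mm slice thickness in mm (bookkeeping only).
#' @return object of class `sequence_params`.
#' @export
#' @examples
#' sagittal <- sequence_params(256, 256, 30, tr_ms = 1000, rare_factor = 1)
#' scan_time(sagittal)  # 256 s
sequence_params <- function(n_read = 128, n_pe = 128, fov_mm = 30,
                            tr_ms = 1000, te_ms = 5, rare_factor = 1L,
                            n_averages = 1L,
                            pe_ordering = c("linear-interleaved", "sequential"),
                            slice_thickness_mm = 1) {
  pe_ordering <- match.arg(pe_ordering)
  stopifnot(n_read >= 8, n_pe >= 8, tr_ms > 0, n_averages >= 1)
  if (rare_factor < 1 || rare_factor > n_pe)
    stop("rare_factor must lie in [1, n_pe]")
  structure(list(n_read = as.integer(n_read), n_pe = as.integer(n_pe),
                 fov_mm = rep(as.numeric(fov_mm), length.out = 2),
                 tr_ms = tr_ms, te_ms = te_ms,
                 rare_factor = as.integer(rare_factor),
                 n_averages = as.integer(n_averages),
                 pe_ordering = pe_ordering,
                 slice_thickness_mm = slice_thickness_mm),
            class = "sequence_params")
}

#' Total acquisition time of a RARE protocol
#'
#' One shot (excitation plus its echo train) acquires `rare_factor`
#' phase-encode lines, so one average needs `floor(n_pe / rare_factor)`
#' shots of one TR each; remainder lines are left unacquired
#' (zero-filled).
#'
#' @param seq a [sequence_params()].
#' @return scan time in seconds.
#' @export
scan_time <- function(seq) {
  stopifnot(inherits(seq, "sequence_params"))
  shots_per_average <- seq$n_pe %/% seq$rare_factor
  shots_per_average * (seq$tr_ms / 1000) * seq$n_averages
}

#' In-plane resolution from FOV and matrix size
#'
#' @param fov_mm field of view in mm.
#' @param n matrix size along the same axis (>= 1).
#' @return list with `exact_um` (`1000 * fov_mm / n`) and `reported_um`
#'   (the integer value as printed in protocol summaries, rounded
#'   half-to-even).
#' @export
#' @examples
#' in_plane_resolution(30, 256)$reported_um  # 117
in_plane_resolution <- function(fov_mm, n) {
  stopifnot(fov_mm > 0, n >= 1)
  exact <- 1000 * fov_mm / n
  list(exact_um = exact, reported_um = round(exact))
}

#' Phase-encode schedule of a RARE acquisition
#'
#' Splits the phase-encode lines of one average into shots of
#' `rare_factor` lines each. With linear-interleaved ordering shot `s`
#' (0-based) acquires lines `{s, s + S, s + 2S, ...}` where
#' `S = floor(n_pe / rare_factor)` is the number of shots; with
#' sequential ordering shot `s` acquires the contiguous block
#' `{s * rare_factor, ...}`. Each line is acquired at most once;
#' remainder lines beyond `S * rare_factor` are never acquired.
#'
#' @param seq a [sequence_params()] (or `n_pe`); when a plain number is
#'   given, `rare_factor` and `ordering` apply.
#' @param rare_factor,ordering used only when `seq` is numeric.
#' @return list of integer vectors of 0-based PE line indices, one per
#'   shot, for one average.
#' @export
#' @examples
#' pe_schedule(8, rare_factor = 4)  # list(c(0,2,4,6), c(1,3,5,7))
pe_schedule <- function(seq, rare_factor = 1L,
                        ordering = c("linear-interleaved", "sequential")) {
  if (inherits(seq, "sequence_params")) {
    n_pe <- seq$n_pe; rare_factor <- seq$rare_factor; ordering <- seq$pe_ordering
  } else {
    n_pe <- as.integer(seq); ordering <- match.arg(ordering)
  }
  rare_factor <- as.integer(rare_factor)
  if (rare_factor < 1 || rare_factor > n_pe)
    stop("rare_factor must lie in [1, n_pe]")
  S <- n_pe %/% rare_factor
  lapply(seq_len(S) - 1L, function(s) {
    if (ordering == "linear-interleaved") s + S * (seq_len(rare_factor) - 1L)
    else s * rare_factor + (seq_len(rare_factor) - 1L)
  })
}

#' Acquire the k-space lines of one shot
#'
#' Computes the 2D discrete Fourier transform of the object frozen at
#' the shot's fire time (inter-scan motion model: motion within the
#' millisecond-scale echo train is neglected) and extracts the requested
#' phase-encode lines. k-space is stored DC-centred (fftshift
#' convention) with PE lines as rows.
#'
#' @param instantaneous_image numeric matrix (rows = PE direction).
#' @param pe_indices integer vector of 0-based PE line indices.
#' @return complex matrix, one row per requested line.
#' @export
acquire_shot <- function(instantaneous_image, pe_indices) {
  K <- fftshift2(stats::fft(instantaneous_image))
  K[pe_indices + 1L, , drop = FALSE]
}

new_kspace <- function(seq) {
  n_lines <- seq$n_pe
  structure(list(samples = matrix(complex(real = 0), seq$n_pe, seq$n_read),
                 line_time_s = rep(NA_real_, n_lines),
                 line_shot = rep(NA_integer_, n_lines),
                 acquired = logical(n_lines),
                 complete = FALSE, seq = seq,
                 layout = "rows are DC-centred phase-encode lines"),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %d x %d, %d/%d lines acquired%s\n",
              nrow(x$samples), ncol(x$samples), sum(x$acquired),
              length(x$acquired),
              if (x$complete) ", complete" else ", INCOMPLETE"))
  invisible(x)
}

#' Acquire a full k-space series from a moving phantom
#'
#' Ungated mode: shots fire every TR starting at t = 0, each sampling
#' the phantom frozen at its fire time. Gated mode: shot fire times and
#' completeness come from a prospectively gated session
#' ([run_gated_session()]); this function is the ungated engine and the
#' shared shot-sampling core.
#'
#' @param seq a [sequence_params()].
#' @param render a [render_phantom()] on the MRI grid
#'   (`n_pe` x `n_read`).
#' @param model a [motion_model()]; `NULL` for a static object.
#' @param noise_sd optional circularly-symmetric complex Gaussian
#'   measurement noise sd per k-space sample (default 0).
#' @param seed seed for the measurement-noise stream.
#' @param t0 start time in seconds of the first shot.
#' @return a `kspace_data` object with per-line timestamps and shot map.
#' @export
acquire_series <- function(seq, render, model = NULL, noise_sd = 0,
                           seed = 1L, t0 = 0) {
  stopifnot(inherits(seq, "sequence_params"))
  if (!all(render$grid == c(seq$n_pe, seq$n_read)))
    stop("phantom render grid must match (n_pe, n_read)")
  shots <- pe_schedule(seq)
  ks <- new_kspace(seq)
  acc <- matrix(complex(real = 0), seq$n_pe, seq$n_read)
  tr_s <- seq$tr_ms / 1000
  shot_idx <- 0L
  for (avg in seq_len(seq$n_averages)) {
    for (s in seq_along(shots)) {
      t_fire <- t0 + shot_idx * tr_s
      tf <- if (is.null(model)) rigid_transform2d() else eval_motion(model, t_fire)
      img <- render_frame(render, tf, t = t_fire)$frame$pixels
      lines <- acquire_shot(img, shots[[s]])
      acc[shots[[s]] + 1L, ] <- acc[shots[[s]] + 1L, ] + lines
      ks$line_time_s[shots[[s]] + 1L] <- t_fire
      ks$line_shot[shots[[s]] + 1L] <- shot_idx
      ks$acquired[shots[[s]] + 1L] <- TRUE
      shot_idx <- shot_idx + 1L
    }
  }
  ks$samples <- acc / seq$n_averages
  if (noise_sd > 0) {
    ks$samples <- ks$samples + with_seed(seed, matrix(
      complex(real = stats::rnorm(length(acc), 0, noise_sd / sqrt(2)),
              imaginary = stats::rnorm(length(acc), 0, noise_sd / sqrt(2))),
      seq$n_pe, seq$n_read))
  }
  ks$complete <- all(ks$acquired[seq_len((seq$n_pe %/% seq$rare_factor) *
                                           seq$rare_factor)])
  ks
}

#' Reconstruct a magnitude image from k-space
#'
#' Magnitude of the inverse 2D DFT of the DC-centred k-space matrix;
#' unacquired lines contribute as zeros.
#'
#' @param kspace a `kspace_data` object or a DC-centred complex matrix.
#' @return object of class `recon_image` with elements `magnitude`
#'   (non-negative matrix) and `provenance`.
#' @export
reconstruct <- function(kspace) {
  K <- if (inherits(kspace, "kspace_data")) kspace$samples else kspace
  img <- stats::fft(ifftshift2(K), inverse = TRUE) / length(K)
  prov <- if (inherits(kspace, "kspace_data")) {
    list(seq = kspace$seq, complete = kspace$complete)
  } else NULL
  structure(list(magnitude = Mod(img), provenance = prov),
            class = "recon_image")
}

#' Build an acquisition engine over a moving phantom
#'
#' Returns a closure `function(t_fire, pe_indices)` that freezes the
#' phantom at `t_fire` and returns the requested complex k-space lines;
#' this is the engine a gated session triggers.
#'
#' @param render a [render_phantom()] on the MRI grid.
#' @param model a [motion_model()] (or `NULL` for static).
#' @return a function `(t_fire, pe_indices) -> complex matrix`.
#' @export
make_acquisition_engine <- function(render, model = NULL) {
  force(render); force(model)
  function(t_fire, pe_indices) {
    tf <- if (is.null(model)) rigid_transform2d() else eval_motion(model, t_fire)
    img <- render_frame(render, tf, t = t_fire)$frame$pixels
    acquire_shot(img, pe_indices)
  }
}
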