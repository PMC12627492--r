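#' Write a frame stack as numbered PNG files with a JSON sidecar
#'
#' Frames are written as zero-padded grayscale PNGs
#' (`frame_000000.png`, ...) with intensities clipped to `[0, 1]`, plus
#' a `stack.json` sidecar holding the frame rate, pixel pitch, seed and
#' frame count.
#'
#' @param frames list of `image_frame`s.
#' @param dir output directory (created if needed).
#' @param frame_rate frames per second recorded in the sidecar.
#' @param seed seed recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_frame_stack <- function(frames, dir, frame_rate = 30, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    png::writePNG(pmin(pmax(f$pixels, 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", k - 1L)))
  }
  meta <- list(n_frames = length(frames),
               frame_rate_hz = frame_rate,
               pixel_pitch_um = frames[[1]]$pixel_pitch_um,
               seed = seed)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param dir directory holding numbered PNGs and `stack.json`.
#' @return list with `frames` (list of `image_frame`) and `meta`.
#' @export
read_frame_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frames found in ", dir)
  frames <- lapply(seq_along(files), function(k) {
    structure(list(pixels = png::readPNG(files[k]),
                   timestamp = (k - 1) / meta$frame_rate_hz,
                   frame_index = k - 1L,
                   pixel_pitch_um = meta$pixel_pitch_um),
              class = "image_frame")
  })
  list(frames = frames, meta = meta)
}

#' Write a keypoint trajectory as CSV
#'
#' Comma-separated, UTF-8, header `frame,t,x,y[,status]`; times in
#' seconds with six decimals, positions in 0-based pixels.
#'
#' @param trajectory data.frame with columns `frame`, `t`, `x`, `y` and
#'   optionally `status`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  out <- trajectory
  out$t <- sprintf("%.6f", out$t)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory or annotation CSV
#' @param path CSV with header `frame,t,x,y[,status]` (annotation tables
#'   may omit `t`).
#' @return data.frame.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a gate log as CSV files
#'
#' Events as `shot,detect_t,fire_t,x,y` plus a `*_state.csv` per-frame
#' gate-state trace.
#'
#' @param gate_log a `gate_log` from [run_gated_session()].
#' @param path events CSV path; the state trace is written next to it.
#' @return `path`, invisibly.
#' @export
write_gate_log <- function(gate_log, path) {
  ev <- gate_log$events
  ev$detect_t <- sprintf("%.6f", ev$detect_t)
  ev$fire_t <- sprintf("%.6f", ev$fire_t)
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  state_path <- sub("\\.csv$", "_state.csv", path)
  st <- gate_log$state
  st$t <- sprintf("%.6f", st$t)
  utils::write.csv(st, state_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write k-space data as a plain-text container directory
#'
#' The container holds the complex samples as paired real/imaginary
#' CSV matrices, the per-line timing and shot map as `lines.csv`, and
#' the sequence parameters and layout as `meta.json`.
#'
#' @param kspace a `kspace_data`.
#' @param dir container directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kspace <- function(kspace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(Re(kspace$samples), file.path(dir, "samples_re.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(Im(kspace$samples), file.path(dir, "samples_im.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(line = seq_along(kspace$acquired) - 1L,
                              time_s = kspace$line_time_s,
                              shot = kspace$line_shot,
                              acquired = kspace$acquired),
                   file.path(dir, "lines.csv"), row.names = FALSE)
  meta <- unclass(kspace$seq)
  meta$complete <- kspace$complete
  meta$layout <- kspace$layout
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a k-space container written by [write_kspace()]
#' @param dir container directory.
#' @return a `kspace_data`.
#' @export
read_kspace <- function(dir) {
  re <- as.matrix(utils::read.table(file.path(dir, "samples_re.csv"), sep = ","))
  im <- as.matrix(utils::read.table(file.path(dir, "samples_im.csv"), sep = ","))
  lines <- utils::read.csv(file.path(dir, "lines.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  seqp <- sequence_params(meta$n_read, meta$n_pe, meta$fov_mm, meta$tr_ms,
                          meta$te_ms, meta$rare_factor, meta$n_averages,
                          meta$pe_ordering, meta$slice_thickness_mm)
  ks <- new_kspace(seqp)
  ks$samples <- matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
  ks$line_time_s <- lines$time_s
  ks$line_shot <- lines$shot
  ks$acquired <- lines$acquired
  ks$complete <- isTRUE(meta$complete)
  ks
}

#' Write a reconstructed magnitude image as PNG
#'
#' @param recon a `recon_image` (or matrix).
#' @param path PNG path; intensities are scaled to the image maximum.
#' @return `path`, invisibly.
#' @export
write_recon_png <- function(recon, path) {
  a <- if (inherits(recon, "recon_image")) recon$magnitude else recon
  mx <- max(a)
  png::writePNG(if (mx > 0) a / mx else a, path)
  invisible(path)
}
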