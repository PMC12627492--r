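#' Euclidean tracking-error benchmark
#'
#' Compares detected keypoint positions against ground-truth (or manual)
#' annotations matched on frame index, exactly as in the 100-image
#' benchmark protocol: per-frame Euclidean distances, their mean and
#' sample standard deviation (n - 1 denominator), the micron
#' equivalents at the given pixel pitch, and an error histogram. Frames
#' whose detection status is `"lost"` are excluded from the statistics
#' and reported as an exclusion count.
#'
#' @param detections trajectory data.frame (`frame`, `x`, `y`, optional
#'   `status`).
#' @param annotations trajectory data.frame (`frame`, `x`, `y`).
#' @param pixel_pitch_um microns per pixel for unit conversion
#'   (default 44.6, the pitch implied by the paired px/um error
#'   reporting of the benchmarked camera geometry).
#' @param n_bins number of uniform histogram bins from 0 to the maximum
#'   distance.
#' @return object of class `tracking_error_report`: `distances_px`,
#'   `distances_um`, `mean_px`, `sd_px`, `mean_um`, `sd_um`, `histogram`
#'   (`breaks`, `counts`), `n_frames`, `n_excluded`, `pixel_pitch_um`.
#' @export
#' @examples
#' det <- data.frame(frame = 0:1, x = c(3, 0), y = c(4, 0))
#' ann <- data.frame(frame = 0:1, x = 0, y = 0)
#' euclidean_errors(det, ann)$distances_px  # 5, 0
euclidean_errors <- function(detections, annotations, pixel_pitch_um = 44.6,
                             n_bins = 10) {
  m <- merge(detections, annotations, by = "frame",
             suffixes = c("_det", "_ann"))
  if (nrow(m) == 0) stop("no overlapping frames between the trajectories")
  lost <- if ("status" %in% names(detections)) {
    m$frame %in% detections$frame[detections$status == "lost"]
  } else rep(FALSE, nrow(m))
  mm <- m[!lost, ]
  if (nrow(mm) == 0) stop("no tracked frames overlap the annotations")
  d <- sqrt((mm$x_det - mm$x_ann)^2 + (mm$y_det - mm$y_ann)^2)
  breaks <- seq(0, max(d, .Machine$double.eps), length.out = n_bins + 1)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(distances_px = d,
                 distances_um = px_to_um(d, pixel_pitch_um),
                 mean_px = mean(d),
                 sd_px = if (length(d) > 1) stats::sd(d) else 0,
                 mean_um = px_to_um(mean(d), pixel_pitch_um),
                 sd_um = px_to_um(if (length(d) > 1) stats::sd(d) else 0,
                                  pixel_pitch_um),
                 histogram = list(breaks = h$breaks, counts = h$counts),
                 n_frames = nrow(mm), n_excluded = sum(lost),
                 pixel_pitch_um = pixel_pitch_um),
            class = "tracking_error_report")
}

#' @export
print.tracking_error_report <- function(x, ...) {
  cat(sprintf(
    "<tracking_error_report> %d frames (%d excluded): %.2f +/- %.2f px (%.0f +/- %.0f um)\n",
    x$n_frames, x$n_excluded, x$mean_px, x$sd_px, x$mean_um, x$sd_um))
  invisible(x)
}

#' Convert a pixel distance to microns
#'
#' @param distance_px distance in pixels.
#' @param pixel_pitch_um microns per pixel (> 0).
#' @return distance in microns.
#' @export
#' @examples
#' px_to_um(2.04, 44.6)  # ~91 um
px_to_um <- function(distance_px, pixel_pitch_um = 44.6) {
  stopifnot(pixel_pitch_um > 0)
  distance_px * pixel_pitch_um
}

#' Root-mean-square error between two images
#'
#' @param image,reference numeric matrices of identical shape (a
#'   `recon_image` is accepted and reduced to its magnitude).
#' @return scalar RMSE.
#' @export
rmse <- function(image, reference) {
  a <- if (inherits(image, "recon_image")) image$magnitude else image
  b <- if (inherits(reference, "recon_image")) reference$magnitude else reference
  if (!all(dim(a) == dim(b))) stop("images must have identical shapes")
  sqrt(mean((a - b)^2))
}

#' Ghost-to-signal ratio
#'
#' Mean absolute intensity in a background region (where ghost replicas
#' of moving structure land) divided by the mean absolute intensity in a
#' signal region; an operational measure of phase-encode ghosting.
#'
#' @param image numeric matrix or `recon_image`.
#' @param signal_roi,background_roi logical masks (same shape as the
#'   image), disjoint and non-empty.
#' @return scalar ratio.
#' @export
ghost_to_signal <- function(image, signal_roi, background_roi) {
  a <- if (inherits(image, "recon_image")) image$magnitude else image
  if (!any(signal_roi) || !any(background_roi)) stop("ROIs must be non-empty")
  if (any(signal_roi & background_roi)) stop("ROIs must be disjoint")
  mean(abs(a[background_roi])) / mean(abs(a[signal_roi]))
}

#' Intensity profile along a line
#'
#' Extracts intensities along a grid row/column or along an arbitrary
#' polyline (bilinear sampling, 0-based pixel coordinates).
#'
#' @param image numeric matrix or `recon_image`.
#' @param axis `"row"` or `"col"` for axis-aligned profiles.
#' @param index 0-based row/column index for axis-aligned profiles.
#' @param polyline optional 2-column matrix of (x, y) sample points
#'   overriding `axis`/`index`.
#' @return numeric vector of sampled intensities.
#' @export
line_profile <- function(image, axis = c("row", "col"), index = 0,
                         polyline = NULL) {
  a <- if (inherits(image, "recon_image")) image$magnitude else image
  if (!is.null(polyline)) {
    polyline <- matrix(polyline, ncol = 2)
    if (min(polyline) < 0 || max(polyline[, 1]) > ncol(a) - 1 ||
        max(polyline[, 2]) > nrow(a) - 1)
      stop("polyline extends outside the image")
    return(bilinear_sample(a, polyline[, 1], polyline[, 2]))
  }
  axis <- match.arg(axis)
  n <- if (axis == "row") nrow(a) else ncol(a)
  if (index < 0 || index > n - 1) stop("profile index out of bounds")
  if (axis == "row") a[index + 1, ] else a[, index + 1]
}

#' Compare reconstructions across acquisition conditions
#'
#' Produces one artifact report per condition against a common
#' motion-free reference: RMSE, ghost-to-signal ratio (when ROIs are
#' given) and a central-column intensity profile, mirroring the
#' inactive / ungated / gated side-by-side comparison.
#'
#' @param reference_recon motion-free reference (`recon_image` or matrix).
#' @param ... named conditions (`recon_image`s or matrices), e.g.
#'   `ungated = ..., gated = ...`.
#' @param signal_roi,background_roi optional logical masks for the ghost
#'   ratio.
#' @param profile_index 0-based column index for the intensity profile
#'   (default: centre column).
#' @return data.frame with one row per condition (`condition`, `rmse`,
#'   `ghost_ratio`), with the per-condition profiles attached as the
#'   `"profiles"` attribute.
#' @export
compare_conditions <- function(reference_recon, ..., signal_roi = NULL,
                               background_roi = NULL, profile_index = NULL) {
  conds <- list(...)
  if (is.null(names(conds)) || any(names(conds) == ""))
    names(conds) <- paste0("condition", seq_along(conds))
  ref <- if (inherits(reference_recon, "recon_image")) {
    reference_recon$magnitude
  } else reference_recon
  profile_index <- profile_index %||% (ncol(ref) %/% 2)
  rows <- lapply(names(conds), function(nm) {
    img <- conds[[nm]]
    g <- if (!is.null(signal_roi) && !is.null(background_roi)) {
      ghost_to_signal(img, signal_roi, background_roi)
    } else NA_real_
    data.frame(condition = nm, rmse = rmse(img, ref), ghost_ratio = g)
  })
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- c(
    list(reference = line_profile(ref, axis = "col", index = profile_index)),
    lapply(conds, line_profile, axis = "col", index = profile_index))
  out
}
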