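#' Segmented 2D insect phantom specification
#'
#' Defines a digital insect as a set of intensity-weighted ellipses
#' (head, thorax, abdomen and optional internal features), together with
#' the thorax--abdomen pivot about which the abdomen flexes and the
#' tracked keypoint on the posterior abdomen boundary.
#'
#' Coordinates are in millimetres in the image frame: the origin is the
#' top-left corner of the field of view, x increases rightward (columns),
#' y increases downward (rows). Positive rotation angles turn +x toward +y.
#'
#' @param segments list of segments, each a list with fields `label`
#'   (one of `"head"`, `"thorax"`, `"abdomen"`, `"internal-feature"`),
#'   `center` (mm, length-2), `semi_axes` (mm, length-2), `intensity`
#'   (in `[0, 1]`), and optional logical `moving` (defaults to `TRUE` for
#'   label `"abdomen"`, else `FALSE`). Moving segments ride on the abdomen.
#' @param pivot length-2 point (mm), the thorax--abdomen junction.
#' @param keypoint length-2 point (mm) on or inside the abdomen; the
#'   location tracked by the computer-vision system.
#' @param body_frame_extent scalar extent (mm) of the body frame; segments
#'   must fit inside `[0, body_frame_extent]^2`.
#' @return an object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- default_insect_phantom()
#' length(spec$segments)
phantom_spec <- function(segments, pivot, keypoint, body_frame_extent = 30) {
  stopifnot(is.list(segments), length(pivot) == 2, length(keypoint) == 2,
            body_frame_extent > 0)
  labs <- c("head", "thorax", "abdomen", "internal-feature")
  segments <- lapply(segments, function(s) {
    stopifnot(s$label %in% labs, length(s$center) == 2,
              length(s$semi_axes) == 2, all(s$semi_axes > 0))
    if (s$intensity < 0 || s$intensity > 1)
      stop("segment intensity must lie in [0, 1]")
    s$moving <- isTRUE(s$moving) || (is.null(s$moving) && s$label == "abdomen")
    s
  })
  structure(list(segments = segments,
                 pivot = as.numeric(pivot),
                 keypoint = as.numeric(keypoint),
                 body_frame_extent = body_frame_extent),
            class = "phantom_spec")
}

#' Default sun-beetle-like phantom
#'
#' A beetle-scale phantom (~25 mm body) in a 30 mm frame: head and thorax
#' static, abdomen plus an internal gut-like feature moving, with the
#' keypoint on the posterior abdomen boundary (the body part tracked by
#' the gating system).
#'
#' @param body_frame_extent frame extent in mm (default 30).
#' @return a [phantom_spec()].
#' @export
default_insect_phantom <- function(body_frame_extent = 30) {
  # body laid out along x, head to the left, abdomen posterior to the right
  phantom_spec(
    segments = list(
      list(label = "head",    center = c(6.0, 15.0), semi_axes = c(2.0, 1.8),
           intensity = 0.55),
      list(label = "thorax",  center = c(11.0, 15.0), semi_axes = c(3.4, 3.0),
           intensity = 0.85),
      list(label = "abdomen", center = c(19.5, 15.0), semi_axes = c(5.5, 4.0),
           intensity = 0.70),
      list(label = "internal-feature", center = c(19.5, 15.0),
           semi_axes = c(3.0, 1.6), intensity = 0.25, moving = TRUE)
    ),
    pivot = c(14.2, 15.0),          # thorax--abdomen junction
    keypoint = c(24.6, 15.0),       # posterior tip of the abdomen
    body_frame_extent = body_frame_extent
  )
}

# Anti-aliased coverage of one axis-aligned ellipse on an n x n grid,
# by ss x ss supersampling per pixel. xs/ys are 0-based pixel-centre mm
# coordinates of columns/rows; delta is the pixel size in mm.
ellipse_coverage <- function(nr, nc, delta, center, semi_axes, ss = 3) {
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss * delta
  cov <- matrix(0, nr, nc)
  xs <- ((seq_len(nc) - 0.5) * delta)  # mm at pixel centres
  ys <- ((seq_len(nr) - 0.5) * delta)
  for (ox in offs) {
    dx2 <- ((xs + ox - center[1]) / semi_axes[1])^2
    for (oy in offs) {
      dy2 <- ((ys + oy - center[2]) / semi_axes[2])^2
      cov <- cov + (outer(dy2, dx2, `+`) <= 1)
    }
  }
  cov / ss^2
}

#' Rasterize a phantom onto a grid
#'
#' Renders the phantom as the sum of its segment ellipse indicator
#' functions weighted by intensity, anti-aliased at the boundaries by
#' supersampling, and returns per-segment masks. Static (head/thorax) and
#' moving (abdomen and attached features) parts are kept as separate
#' layers so frames under motion can be composed by warping only the
#' moving layer.
#'
#' @param spec a [phantom_spec()].
#' @param grid integer or length-2 integer, output grid size
#'   (rows, cols); a scalar means a square grid.
#' @param fov_mm field of view in mm (scalar, square FOV). Defaults to
#'   the spec's body frame extent.
#' @return an object of class `phantom_render` with elements `image`
#'   (static + moving), `static_img`, `moving_img`, `masks` (named list of
#'   logical matrices, one per segment, later segments claiming overlapped
#'   pixels), `delta_mm` (pixel size), `pixel_pitch_um`, `grid`, `fov_mm`,
#'   and the originating `spec`.
#' @export
#' @examples
#' ph <- render_phantom(default_insect_phantom(), grid = 64)
#' range(ph$image)
render_phantom <- function(spec, grid = 128, fov_mm = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  fov_mm <- fov_mm %||% spec$body_frame_extent
  grid <- as.integer(rep(grid, length.out = 2))
  if (any(grid < 16)) stop("grid dimensions must be at least 16")
  nr <- grid[1]; nc <- grid[2]
  delta <- fov_mm / nc   # square pixels; FOV along x
  static_img <- matrix(0, nr, nc)
  moving_img <- matrix(0, nr, nc)
  masks <- list()
  claimed <- matrix(0L, nr, nc)
  for (i in seq_along(spec$segments)) {
    s <- spec$segments[[i]]
    lo <- s$center - s$semi_axes
    hi <- s$center + s$semi_axes
    if (any(lo < 0) || hi[1] > nc * delta || hi[2] > nr * delta)
      stop(sprintf("segment '%s' lies outside the field of view", s$label))
    cov <- ellipse_coverage(nr, nc, delta, s$center, s$semi_axes)
    if (s$moving) moving_img <- moving_img + s$intensity * cov
    else          static_img <- static_img + s$intensity * cov
    claimed[cov > 0.5] <- i
    masks[[i]] <- NULL
  }
  mask_list <- lapply(seq_along(spec$segments), function(i) claimed == i)
  names(mask_list) <- vapply(spec$segments, `[[`, "", "label")
  structure(list(image = static_img + moving_img,
                 static_img = static_img, moving_img = moving_img,
                 masks = mask_list, delta_mm = delta,
                 pixel_pitch_um = delta * 1000,
                 grid = grid, fov_mm = fov_mm, spec = spec),
            class = "phantom_render")
}

#' @export
print.phantom_render <- function(x, ...) {
  cat(sprintf("<phantom_render> %d x %d px, FOV %.1f mm (%.1f um/px), %d segments\n",
              x$grid[1], x$grid[2], x$fov_mm, x$pixel_pitch_um,
              length(x$spec$segments)))
  invisible(x)
}

#' In-plane rigid transform (rotation about a pivot plus translation)
#'
#' @param rotation_angle angle in radians; positive rotates +x toward +y
#'   in the image frame (x right, y down).
#' @param translation length-2 translation in mm.
#' @return object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(rotation_angle = 0, translation = c(0, 0)) {
  stopifnot(length(rotation_angle) == 1, length(translation) == 2)
  structure(list(rotation_angle = rotation_angle,
                 translation = as.numeric(translation)),
            class = "rigid_transform2d")
}

#' Test whether a transform is the identity
#' @param tf a [rigid_transform2d()].
#' @param tol absolute tolerance.
#' @return logical.
#' @export
is_identity_transform <- function(tf, tol = 1e-12) {
  abs(tf$rotation_angle) <= tol && all(abs(tf$translation) <= tol)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform2d()]; inversion is with respect to the
#'   same pivot the forward transform is applied about.
#' @return the inverse `rigid_transform2d` such that composing forward and
#'   inverse (about the same pivot) is the identity map.
#' @export
invert_transform <- function(tf) {
  th <- tf$rotation_angle
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # columns
  # forward: p' = R (p - c) + c + t  =>  inverse: p = R^-1 (p' - t - c) + c
  # expressed again as rotation about the pivot with a translation:
  # p = R^-1 (p' - c) + c + (R^-1 (c - t - c) - (c - c)) ... keep it simple:
  # inverse rotation -th about pivot, translation chosen so that the
  # composition cancels: t_inv = R^-1 (-t)
  Rinv <- t(R)
  rigid_transform2d(-th, as.numeric(Rinv %*% (-tf$translation)))
}

#' Apply a rigid transform to a point
#'
#' Rotates `point_mm` about `pivot` by the transform's angle (positive
#' angle turns +x toward +y), then translates.
#'
#' @param tf a [rigid_transform2d()].
#' @param point_mm length-2 point or 2-column matrix of points (mm).
#' @param pivot length-2 pivot (mm).
#' @return transformed point(s), same shape as `point_mm`.
#' @export
#' @examples
#' tf <- rigid_transform2d(pi / 2)
#' apply_transform(tf, c(1, 0), pivot = c(0, 0))  # ~ (0, 1)
apply_transform <- function(tf, point_mm, pivot) {
  th <- tf$rotation_angle
  ct <- cos(th); st <- sin(th)
  p <- matrix(point_mm, ncol = 2)
  px <- p[, 1] - pivot[1]
  py <- p[, 2] - pivot[2]
  out <- cbind(ct * px - st * py + pivot[1] + tf$translation[1],
               st * px + ct * py + pivot[2] + tf$translation[2])
  if (is.null(dim(point_mm))) as.numeric(out) else out
}

# mm <-> 0-based pixel-centre coordinates
mm_to_px <- function(p_mm, delta) p_mm / delta - 0.5
px_to_mm <- function(p_px, delta) (p_px + 0.5) * delta

#' Render one camera frame under a rigid abdomen pose
#'
#' Composes the static (head/thorax) layer with the moving (abdomen)
#' layer warped to the given pose, by inverse-mapping bilinear sampling
#' (samples outside the grid read as 0), then adds zero-mean Gaussian
#' noise drawn from the current RNG stream. Ground truth is the
#' transformed keypoint in 0-based pixel coordinates.
#'
#' @param render a [render_phantom()] result.
#' @param tf a [rigid_transform2d()] abdomen pose.
#' @param t timestamp in seconds.
#' @param frame_index integer frame index (0-based).
#' @param noise_sd additive Gaussian noise sd (intensity units, >= 0).
#' @return list with `frame` (class `image_frame`: `pixels`, `timestamp`,
#'   `frame_index`, `pixel_pitch_um`) and `keypoint_px` (length-2,
#'   0-based x, y).
#' @export
render_frame <- function(render, tf, t = 0, frame_index = 0L, noise_sd = 0) {
  stopifnot(inherits(render, "phantom_render"), noise_sd >= 0)
  nr <- render$grid[1]; nc <- render$grid[2]
  if (is_identity_transform(tf)) {
    mov <- render$moving_img
  } else {
    inv <- invert_transform(tf)
    # destination pixel centres in mm
    xs <- px_to_mm(0:(nc - 1), render$delta_mm)
    ys <- px_to_mm(0:(nr - 1), render$delta_mm)
    X <- matrix(xs, nr, nc, byrow = TRUE)
    Y <- matrix(ys, nr, nc)
    src <- apply_transform(inv, cbind(as.numeric(X), as.numeric(Y)),
                           render$spec$pivot)
    sx <- mm_to_px(src[, 1], render$delta_mm)
    sy <- mm_to_px(src[, 2], render$delta_mm)
    mov <- matrix(bilinear_sample(render$moving_img, sx, sy), nr, nc)
  }
  px <- render$static_img + mov
  if (noise_sd > 0)
    px <- px + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  kp_mm <- apply_transform(tf, render$spec$keypoint, render$spec$pivot)
  frame <- structure(list(pixels = px, timestamp = t,
                          frame_index = as.integer(frame_index),
                          pixel_pitch_um = render$pixel_pitch_um),
                     class = "image_frame")
  list(frame = frame, keypoint_px = mm_to_px(kp_mm, render$delta_mm))
}

as_pixels <- function(x) {
  if (inherits(x, "image_frame")) x$pixels else as.matrix(x)
}
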