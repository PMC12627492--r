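#' Spatial intensity gradients of a frame
#'
#' Central differences in the interior; plain one-sided differences at
#' the image borders. Units are intensity per pixel. These are the
#' `dI/dx`, `dI/dy` terms of the optical-flow constraint equation.
#'
#' @param frame an `image_frame` or numeric matrix (rows = y, cols = x).
#' @return list with matrices `Ix`, `Iy` of the same shape.
#' @export
#' @examples
#' I <- outer(0:9, 0:9, function(y, x) 2 * x + 3 * y)
#' g <- spatial_gradients(I)
#' g$Ix[5, 5]; g$Iy[5, 5]  # 2 and 3
spatial_gradients <- function(frame) {
  I <- as_pixels(frame)
  nr <- nrow(I); nc <- ncol(I)
  if (nr < 3 || nc < 3) stop("frame must be at least 3 x 3")
  Ix <- matrix(0, nr, nc)
  Ix[, 2:(nc - 1)] <- (I[, 3:nc] - I[, 1:(nc - 2)]) / 2
  Ix[, 1] <- I[, 2] - I[, 1]
  Ix[, nc] <- I[, nc] - I[, nc - 1]
  Iy <- matrix(0, nr, nc)
  Iy[2:(nr - 1), ] <- (I[3:nr, ] - I[1:(nr - 2), ]) / 2
  Iy[1, ] <- I[2, ] - I[1, ]
  Iy[nr, ] <- I[nr, ] - I[nr - 1, ]
  list(Ix = Ix, Iy = Iy)
}

#' Temporal intensity gradient between two frames
#'
#' One-frame difference `I_b - I_a`; the time unit is one frame, so flow
#' vectors solved against it are in pixels per frame.
#'
#' @param frame_a,frame_b frames (matrices or `image_frame`s) of
#'   identical shape.
#' @return matrix `It`.
#' @export
temporal_gradient <- function(frame_a, frame_b) {
  a <- as_pixels(frame_a); b <- as_pixels(frame_b)
  if (!all(dim(a) == dim(b))) stop("frames must have identical shapes")
  b - a
}

#' Assemble the windowed optical-flow least-squares system
#'
#' Builds `A` (one row of `(Ix, Iy)` per window pixel) and `b` (`-It` over
#' the same pixels, same ordering) for the `(2 * window_halfwidth + 1)^2`
#' pixels centred on `center`. Non-integer centres sample the gradient
#' fields by bilinear interpolation.
#'
#' @param gradients list with `Ix`, `Iy`, `It` matrices on the frame grid.
#' @param center length-2 centre in 0-based pixels (x, y).
#' @param window_halfwidth half-width in pixels (>= 1).
#' @return object of class `flow_system`: `A` (n x 2), `b` (n),
#'   `window_halfwidth`, `center`.
#' @export
assemble_system <- function(gradients, center, window_halfwidth = 7) {
  stopifnot(window_halfwidth >= 1, length(center) == 2)
  nr <- nrow(gradients$Ix); nc <- ncol(gradients$Ix)
  hw <- window_halfwidth
  off <- -hw:hw
  xs <- rep(center[1] + off, each = 2 * hw + 1)
  ys <- rep(center[2] + off, times = 2 * hw + 1)
  if (min(xs) < 0 || max(xs) > nc - 1 || min(ys) < 0 || max(ys) > nr - 1)
    stop_mocogate("tracking window extends outside the frame",
                  "mocogate_window_error")
  samp <- function(M) bilinear_sample(M, xs, ys)
  structure(list(A = cbind(samp(gradients$Ix), samp(gradients$Iy)),
                 b = -samp(gradients$It),
                 window_halfwidth = hw, center = as.numeric(center)),
            class = "flow_system")
}

#' Default minimum-eigenvalue threshold
#'
#' Scale-aware default `1e-4 * n` for an `n`-pixel window, rejecting
#' aperture-limited (rank-deficient) windows.
#' @param window_halfwidth window half-width in pixels.
#' @return threshold on the smallest eigenvalue of `A^T A`.
#' @export
default_min_eig <- function(window_halfwidth = 7) {
  1e-4 * (2 * window_halfwidth + 1)^2
}

#' Solve the Lucas-Kanade normal equations
#'
#' Computes the flow vector `v = (A^T A)^{-1} A^T b` (the Moore-Penrose
#' pseudoinverse solution of `A v = b`) when the smallest eigenvalue of
#' `A^T A` clears the conditioning threshold; otherwise reports the flow
#' as undefined (the aperture problem) rather than solving a
#' near-singular system.
#'
#' @param system a [assemble_system()] result (or any list with `A`, `b`).
#' @param min_eig_threshold smallest-eigenvalue cutoff; defaults to the
#'   scale-aware [default_min_eig()] for the system's window.
#' @return object of class `flow_vector`: `u`, `v` (px/frame; `NA` when
#'   undefined), `min_eigenvalue`, `residual` (`||A v - b||_2`), `status`
#'   (`"ok"` or `"undefined"`).
#' @export
lk_solve <- function(system, min_eig_threshold = NULL) {
  A <- system$A; b <- system$b
  if (is.null(min_eig_threshold))
    min_eig_threshold <- default_min_eig(system$window_halfwidth %||% 7)
  G <- crossprod(A)            # A^T A, 2 x 2 symmetric
  tr <- G[1, 1] + G[2, 2]
  det <- G[1, 1] * G[2, 2] - G[1, 2]^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  min_eig <- tr / 2 - disc
  if (min_eig < min_eig_threshold) {
    return(structure(list(u = NA_real_, v = NA_real_,
                          min_eigenvalue = min_eig, residual = NA_real_,
                          status = "undefined"),
                     class = "flow_vector"))
  }
  v <- solve(G, crossprod(A, b))
  structure(list(u = v[1], v = v[2], min_eigenvalue = min_eig,
                 residual = sqrt(sum((A %*% v - b)^2)), status = "ok"),
            class = "flow_vector")
}

# 2x downsampling by 2x2 block averaging (pyramid level construction)
downsample2 <- function(I) {
  nr <- 2 * (nrow(I) %/% 2); nc <- 2 * (ncol(I) %/% 2)
  I <- I[seq_len(nr), seq_len(nc)]
  0.25 * (I[seq(1, nr, 2), seq(1, nc, 2)] + I[seq(2, nr, 2), seq(1, nc, 2)] +
            I[seq(1, nr, 2), seq(2, nc, 2)] + I[seq(2, nr, 2), seq(2, nc, 2)])
}

#' Default tracker parameters
#'
#' @param window_halfwidth window half-width in pixels (15 x 15 window by
#'   default, a standard sparse Lucas-Kanade choice).
#' @param max_iters maximum iterative-warp refinement steps per level.
#' @param conv_tol_px convergence threshold on the update norm (px).
#' @param pyramid_levels number of resolution levels (1 = no pyramid).
#' @param min_eig_threshold conditioning cutoff; `NULL` for the
#'   scale-aware default.
#' @return list of parameters.
#' @export
tracker_params <- function(window_halfwidth = 7, max_iters = 10,
                           conv_tol_px = 0.01, pyramid_levels = 2,
                           min_eig_threshold = NULL) {
  list(window_halfwidth = window_halfwidth, max_iters = max_iters,
       conv_tol_px = conv_tol_px, pyramid_levels = pyramid_levels,
       min_eig_threshold = min_eig_threshold)
}

# Single-level iterative LK at one pyramid level; returns list(d, flow, ok).
# Gradients are taken from the moving frame, sampled at the warped window
# (forward-additive scheme), so a feature that vanishes from the new frame
# is reported as aperture-undefined rather than solved against stale
# structure.
lk_refine <- function(Ia, Ib, point, d0, hw, max_iters, tol, min_eig) {
  g <- spatial_gradients(Ib)
  off <- -hw:hw
  xs <- rep(point[1] + off, each = 2 * hw + 1)
  ys <- rep(point[2] + off, times = 2 * hw + 1)
  nr <- nrow(Ia); nc <- ncol(Ia)
  if (min(xs) < 0 || max(xs) > nc - 1 || min(ys) < 0 || max(ys) > nr - 1)
    return(list(d = d0, flow = NULL, ok = FALSE))
  Tpl <- bilinear_sample(Ia, xs, ys)
  d <- d0
  flow <- NULL
  span <- 2 * hw + 1
  for (it in seq_len(max_iters)) {
    wx <- xs + d[1]; wy <- ys + d[2]
    # out-of-frame warped samples read 0; divergence check below bounds d
    A <- cbind(bilinear_sample(g$Ix, wx, wy), bilinear_sample(g$Iy, wx, wy))
    W <- bilinear_sample(Ib, wx, wy)
    flow <- lk_solve(list(A = A, b = -(W - Tpl), window_halfwidth = hw),
                     min_eig_threshold = min_eig)
    if (flow$status != "ok") return(list(d = d, flow = flow, ok = FALSE))
    d <- d + c(flow$u, flow$v)
    if (sqrt(sum(d^2)) > span) return(list(d = d, flow = flow, ok = FALSE))
    if (sqrt(flow$u^2 + flow$v^2) < tol) break
  }
  list(d = d, flow = flow, ok = TRUE)
}

#' Track a keypoint across one frame pair
#'
#' Pyramidal, iterative Lucas-Kanade step: at each resolution level the
#' windowed normal-equation solve is repeated, warping the sampling
#' window of the second frame by the accumulated displacement (bilinear),
#' until the update norm falls below `conv_tol_px` or `max_iters` is
#' reached. Tracking fails (status `"lost"`, position frozen at the input
#' point) when the flow is aperture-undefined, the window leaves the
#' frame, or the displacement diverges beyond the window span.
#'
#' @param frame_a,frame_b consecutive frames.
#' @param point length-2 position in 0-based pixels (x, y) in `frame_a`.
#' @param params a [tracker_params()] list.
#' @return list with `position` (length-2), `flow` (the final
#'   [lk_solve()] result at full resolution, possibly `NULL` when the
#'   window never fit), and `status` (`"tracked"` or `"lost"`).
#' @export
track_step <- function(frame_a, frame_b, point, params = tracker_params()) {
  Ia <- as_pixels(frame_a); Ib <- as_pixels(frame_b)
  hw <- params$window_halfwidth
  L <- params$pyramid_levels
  # build pyramids (level 1 = full resolution); drop levels too small
  pyr_a <- list(Ia); pyr_b <- list(Ib)
  while (length(pyr_a) < L &&
         min(dim(pyr_a[[length(pyr_a)]])) >= 4 * (2 * hw + 1)) {
    pyr_a[[length(pyr_a) + 1]] <- downsample2(pyr_a[[length(pyr_a)]])
    pyr_b[[length(pyr_b) + 1]] <- downsample2(pyr_b[[length(pyr_b)]])
  }
  d <- c(0, 0)
  flow <- NULL
  for (lev in rev(seq_along(pyr_a))) {
    sc <- 2^(lev - 1)
    # pixel centres at level L sit at ((p + 0.5) / sc) - 0.5 in level coords
    p_lev <- (point + 0.5) / sc - 0.5
    res <- lk_refine(pyr_a[[lev]], pyr_b[[lev]], p_lev, d / sc, hw,
                     params$max_iters, params$conv_tol_px / sc,
                     params$min_eig_threshold)
    if (lev == 1) {
      flow <- res$flow
      if (!res$ok)
        return(list(position = point, flow = flow, status = "lost"))
      d <- res$d
    } else {
      # coarse failure is tolerable; keep whatever estimate we have
      d <- res$d * sc
    }
  }
  list(position = point + d, flow = flow, status = "tracked")
}

#' Track a keypoint through a frame sequence
#'
#' Chains [track_step()] frame to frame. When a step is lost the position
#' is frozen at the last good estimate (the conservative choice for
#' gating, where a closed gate is the safe failure mode) and
#' re-acquisition is attempted on subsequent frames by tracking from the
#' last successfully tracked frame, not from the lost one.
#'
#' @param frames list of frames (>= 2).
#' @param initial_point length-2 starting position in 0-based pixels.
#' @param params a [tracker_params()] list.
#' @return a trajectory data.frame with columns `frame`, `t`, `x`, `y`,
#'   `status` (`"tracked"`/`"lost"`); frame 0 carries the initial point.
#' @export
track_sequence <- function(frames, initial_point, params = tracker_params()) {
  stopifnot(length(frames) >= 2)
  n <- length(frames)
  get_t <- function(f, k) if (inherits(f, "image_frame")) f$timestamp else k - 1
  out <- data.frame(frame = seq_len(n) - 1L,
                    t = vapply(seq_len(n), function(k) get_t(frames[[k]], k), 0),
                    x = NA_real_, y = NA_real_,
                    status = "tracked", stringsAsFactors = FALSE)
  pos <- as.numeric(initial_point)
  out$x[1] <- pos[1]; out$y[1] <- pos[2]
  ref <- frames[[1]]   # last good template frame
  for (k in 2:n) {
    st <- track_step(ref, frames[[k]], pos, params)
    if (st$status == "tracked") {
      pos <- st$position
      ref <- frames[[k]]
    }
    out$x[k] <- pos[1]; out$y[k] <- pos[2]
    out$status[k] <- if (st$status == "tracked") "tracked" else "lost"
  }
  out
}
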