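# Shared fixtures: analytic textures and small phantom scenes, all
# generated in code.

# Continuous band-limited texture as a closure: tex(dx, dy) returns the
# n x n image of the texture translated by (dx, dy) pixels (periodic in
# n), evaluated analytically so shifted frames carry no interpolation
# error.
make_texture_fn <- function(n = 64, n_comp = 6, max_freq = 5, seed = 1) {
  set.seed(seed)
  fx <- sample(seq_len(max_freq), n_comp, replace = TRUE) / n
  fy <- sample(seq_len(max_freq), n_comp, replace = TRUE) / n
  phx <- runif(n_comp, 0, 2 * pi)
  phy <- runif(n_comp, 0, 2 * pi)
  amp <- runif(n_comp, 0.3, 1)
  function(dx = 0, dy = 0) {
    xs <- 0:(n - 1)
    img <- matrix(0, n, n)
    for (k in seq_len(n_comp)) {
      img <- img + amp[k] * outer(sin(2 * pi * fy[k] * (xs - dy) + phy[k]),
                                  sin(2 * pi * fx[k] * (xs - dx) + phx[k]))
    }
    0.5 + img / (2.5 * n_comp)
  }
}

# Wrap a plain matrix as an image frame with a timestamp.
as_frame <- function(pixels, t = 0, k = 0L) {
  structure(list(pixels = pixels, timestamp = t, frame_index = as.integer(k),
                 pixel_pitch_um = 100),
            class = "image_frame")
}

# Integer circular shift of a matrix by (dx cols, dy rows).
circshift <- function(m, dx = 0, dy = 0) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# Independent least-squares solution of A v = b via SVD (oracle for the
# normal-equations path in lk_solve).
svd_lstsq <- function(A, b) {
  s <- svd(A)
  as.numeric(s$v %*% ((crossprod(s$u, b)) / s$d))
}

# Naive O(N^4) DC-centred 2D DFT (oracle for acquire_shot).
naive_dft2 <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  K <- matrix(complex(real = 0), n1, n2)
  for (r in seq_len(n1)) {
    ky <- r - 1 - n1 %/% 2
    for (cc in seq_len(n2)) {
      kx <- cc - 1 - n2 %/% 2
      s <- 0 + 0i
      for (y in seq_len(n1) - 1) {
        for (x in seq_len(n2) - 1) {
          s <- s + img[y + 1, x + 1] *
            exp(-2i * pi * (ky * y / n1 + kx * x / n2))
        }
      }
      K[r, cc] <- s
    }
  }
  K
}

# Small camera scene shared by tracking and gating tests: 64 px camera
# view of the default insect phantom.
small_scene <- function(grid = 64) {
  spec <- default_insect_phantom()
  render_phantom(spec, grid = grid)
}
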