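# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded components do not perturb the caller's
#' random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Expand a master seed into per-subsystem seeds
#'
#' Deterministically derives independent integer seeds (one per requested
#' name) from a single master seed, so one number reproduces a whole run.
#'
#' @param master_seed integer master seed.
#' @param names character vector of subsystem names.
#' @return named integer vector of seeds in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' expand_seed(1, c("motion", "camera"))
expand_seed <- function(master_seed, names) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed))
  s <- with_seed(master_seed, sample.int(.Machine$integer.max - 1L, length(names)))
  stats::setNames(s, names)
}

# Bilinear sampling of matrix `img` at continuous 0-based pixel coordinates.
# x is the column coordinate, y the row coordinate, both pixel-center based
# (pixel (0,0) has its center at x = 0, y = 0). Samples outside the grid
# read as 0.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  # value at integer (xi, yi), 0 outside
  pick <- function(xi, yi) {
    ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
    v <- numeric(length(xi))
    idx <- (xi[ok]) * nr + yi[ok] + 1  # column-major, 0-based row yi
    v[ok] <- img[idx]
    v
  }
  (1 - fx) * (1 - fy) * pick(x0,     y0) +
    fx     * (1 - fy) * pick(x0 + 1, y0) +
    (1 - fx) * fy     * pick(x0,     y0 + 1) +
    fx     * fy       * pick(x0 + 1, y0 + 1)
}

# Swap quadrants so the DC component moves to the matrix centre
# (row/col index floor(n/2) + 1) and back. Standard fftshift pair.
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq(floor(nr / 2) + 1, nr), seq_len(floor(nr / 2))),
    c(seq(floor(nc / 2) + 1, nc), seq_len(floor(nc / 2)))]
}

ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq(ceiling(nr / 2) + 1, nr), seq_len(ceiling(nr / 2))),
    c(seq(ceiling(nc / 2) + 1, nc), seq_len(ceiling(nc / 2)))]
}

stop_mocogate <- function(msg, class) {
  stop(structure(class = c(class, "mocogate_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
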