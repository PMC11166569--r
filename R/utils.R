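#' @keywords internal
"_PACKAGE"

## Unit conversion: 1 mbar = 100 Pa = 0.1 nN / um^2
MBAR_TO_NN_PER_UM2 <- 0.1
## 1 Pa * um^2 = 1e-3 nN
PA_UM2_TO_NN <- 1e-3

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are deterministic given a
#' seed without disturbing the caller's RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

#' Separable Gaussian low-pass filter of a 2D image
#'
#' Plain convolution with a truncated Gaussian kernel (reflected borders).
#'
#' @param img numeric matrix.
#' @param sigma kernel standard deviation in pixels; `0` returns `img`.
#' @return filtered matrix of the same dimensions.
#' @keywords internal
gaussian_blur <- function(img, sigma = 1) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_reflect <- function(v, r) c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1L]))
  conv1 <- function(v) {
    vp <- pad_reflect(v, r)
    stats::filter(vp, k, sides = 2)[(r + 1L):(r + length(v))]
  }
  out <- apply(img, 2L, conv1)
  out <- t(apply(out, 1L, conv1))
  matrix(as.numeric(out), nrow(img), ncol(img))
}

## 3x3 neighborhood sum of a logical matrix (zero-padded borders)
neighborhood_sum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0L, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    out <- out + p[(1L + di):(nr + di), (1L + dj):(nc + dj)]
  out
}

## distance (in pixels) of every pixel from an origin; origin given as
## (row, col), 1-based.  Returns a matrix matching dim.
pixel_distances <- function(nr, nc, origin) {
  dr <- matrix(seq_len(nr) - origin[1L], nr, nc)
  dc <- matrix(rep(seq_len(nc) - origin[2L], each = nr), nr, nc)
  sqrt(dr^2 + dc^2)
}
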