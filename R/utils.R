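# Internal low-level helpers shared across modules.

# Shift a matrix by (dy, dx); vacated cells get `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- seq_len(h); xs <- seq_len(w)
  ysrc <- ys - dy; xsrc <- xs - dx
  yok <- ysrc >= 1 & ysrc <= h
  xok <- xsrc >= 1 & xsrc <= w
  if (any(yok) && any(xok)) {
    out[ys[yok], xs[xok]] <- m[ysrc[yok], xsrc[xok]]
  }
  out
}

# Replicate-pad a matrix by (ry, rx) on each side (edge extension).
pad_replicate <- function(m, ry, rx) {
  h <- nrow(m); w <- ncol(m)
  yi <- c(rep(1L, ry), seq_len(h), rep(h, ry))
  xi <- c(rep(1L, rx), seq_len(w), rep(w, rx))
  m[yi, xi, drop = FALSE]
}

# Reflect-pad (mirror without repeating the edge row) to reach exact target
# dims; used to make images divisible by a CLAHE tile grid.
pad_reflect_to <- function(m, target_h, target_w) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(target_h >= h, target_w >= w)
  refl_idx <- function(n, extra) {
    if (extra == 0L) return(seq_len(n))
    if (n == 1L) return(rep(1L, n + extra))
    c(seq_len(n), n - seq_len(extra))
  }
  m[refl_idx(h, target_h - h), refl_idx(w, target_w - w), drop = FALSE]
}

# Separable 2D convolution with replicate boundary handling.
# ky convolves along rows (y axis), kx along columns (x axis). Kernels must
# have odd length. Implemented as shift-and-accumulate, vectorised per tap.
conv_sep <- function(img, ky, kx) {
  ry <- (length(ky) - 1L) %/% 2L
  rx <- (length(kx) - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  p <- pad_replicate(img, ry, rx)
  # y pass
  acc <- matrix(0, h, ncol(p))
  for (i in seq_along(ky)) {
    if (ky[i] != 0) acc <- acc + ky[i] * p[(i):(i + h - 1L), , drop = FALSE]
  }
  # x pass
  out <- matrix(0, h, w)
  for (j in seq_along(kx)) {
    if (kx[j] != 0) out <- out + kx[j] * acc[, (j):(j + w - 1L), drop = FALSE]
  }
  out
}

# Sampled Gaussian and its first two derivatives; radius 4*sigma captures
# >99.99% of mass. order 0 kernels are renormalised to unit sum.
gauss_kernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  k <- switch(as.character(order),
    "0" = g / sum(g),
    "1" = -x / sigma^2 * g,
    "2" = (x^2 - sigma^2) / sigma^4 * g,
    stop("unsupported derivative order")
  )
  k
}

# Gaussian blur (order-0 separable convolution); sigma 0 is the identity.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma, 0L)
  conv_sep(img, k, k)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Coordinates of foreground pixels in raster order
#'
#' Returns 0-based (y, x) rows for TRUE pixels, ordered top-to-bottom then
#' left-to-right — the package's canonical pixel ordering.
#'
#' @param mask Logical matrix.
#' @return Two-column matrix with columns `y`, `x`.
#' @export
which_yx <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("y", "x"))))
  }
  h <- nrow(mask)
  y <- (idx - 1L) %% h
  x <- (idx - 1L) %/% h
  o <- order(y, x)
  cbind(y = y[o], x = x[o])
}

#' Convert 0-based (y, x) coordinates to matrix indices
#'
#' @param yx Two-column matrix of 0-based (y, x) coordinates.
#' @param h Image height (number of matrix rows).
#' @return Integer vector of column-major matrix indices.
#' @export
yx_to_idx <- function(yx, h) {
  as.integer(yx[, 1] + 1 + yx[, 2] * h)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "zv_mask")) x <- x$pixels
  if (inherits(x, "zv_skeleton")) x <- x$skeleton
  if (!is.matrix(x)) stop("expected a matrix or zv_mask/zv_skeleton object")
  if (!is.logical(x)) x <- x != 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
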