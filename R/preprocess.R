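# Projection pre-processing: linear 8-bit normalisation, contrast-limited
# adaptive histogram equalisation, and the initial Otsu vessel mask.

#' Pre-processing parameters
#'
#' @param clahe_clip_limit CLAHE relative clip limit (> 0). Default 2.0.
#' @param clahe_tile_grid Integer pair, tiles in (y, x). Default c(4, 4).
#' @param otsu_enabled Whether the Otsu mask participates in refinement.
#' @export
preprocess_params <- function(clahe_clip_limit = 2.0,
                              clahe_tile_grid = c(4L, 4L),
                              otsu_enabled = TRUE) {
  if (clahe_clip_limit <= 0) stop("clahe_clip_limit must be > 0")
  clahe_tile_grid <- as.integer(clahe_tile_grid)
  if (length(clahe_tile_grid) != 2L || any(clahe_tile_grid < 1L))
    stop("clahe_tile_grid must be two integers >= 1")
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = clahe_tile_grid,
                 otsu_enabled = isTRUE(otsu_enabled)),
            class = "zv_preprocess_params")
}

#' Normalise a projection to 8-bit
#'
#' Linear min-max stretch: the image minimum maps to 0, the maximum to 255,
#' rounded half-to-even. Constant images map to all-zero by convention.
#' The map is invariant to positive affine rescaling of the input.
#'
#' @param image A `zv_projection`.
#' @return An 8-bit `zv_projection`.
#' @export
normalize_to_8bit <- function(image) {
  stopifnot(inherits(image, "zv_projection"))
  px <- image$pixels
  if (length(px) == 0L) stop("empty image")
  lo <- min(px); hi <- max(px)
  out <- if (hi > lo) round((px - lo) / (hi - lo) * 255) else px * 0
  projection_image(out, bit_depth = 8, pixel_size_um = image$pixel_size_um,
                   z_depth_um = image$z_depth_um, channel = image$channel)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Tile-wise histogram equalisation with clipping and bilinear interpolation
#' between tile mappings (Zuiderveld's algorithm, via EBImage). Images whose
#' dimensions are not divisible by the tile grid are mirror-padded for
#' tiling and cropped back, avoiding boundary artefacts.
#'
#' @param image An 8-bit `zv_projection`.
#' @param params A [preprocess_params()] object.
#' @return An 8-bit `zv_projection`.
#' @export
apply_clahe <- function(image, params = preprocess_params()) {
  stopifnot(inherits(image, "zv_projection"))
  if (image$bit_depth != 8) stop("apply_clahe expects an 8-bit image")
  px <- image$pixels
  if (max(px) == min(px)) return(image)  # no contrast to redistribute
  ny <- params$clahe_tile_grid[1]; nx <- params$clahe_tile_grid[2]
  if (ny * nx < 4)
    stop("CLAHE needs at least 4 contextual tiles (ny * nx >= 4)")
  h <- nrow(px); w <- ncol(px)
  # EBImage tiles must be at least 2 px and divide the image exactly
  th <- ceiling(h / ny); tw <- ceiling(w / nx)
  H <- th * ny; W <- tw * nx
  pad <- pad_reflect_to(px, H, W)
  eq <- EBImage::clahe(pad / 255, nx = nx, ny = ny, bins = 256,
                       limit = params$clahe_clip_limit, keep.range = TRUE)
  out <- round(pmin(pmax(matrix(as.numeric(eq), H, W)[seq_len(h), seq_len(w)],
                         0), 1) * 255)
  projection_image(out, bit_depth = 8, pixel_size_um = image$pixel_size_um,
                   z_depth_um = image$z_depth_um, channel = image$channel)
}

#' Otsu threshold of an 8-bit image
#'
#' Exhaustive 256-bin Otsu: returns the threshold t in 0..254 maximising
#' the between-class variance of the split (<= t) vs (> t); ties take the
#' lowest t. Returns NA for constant images (no variance to split).
#'
#' @param image An 8-bit `zv_projection` or integer matrix in 0..255.
#' @return Integer threshold, or NA_integer_.
#' @export
otsu_threshold <- function(image) {
  px <- if (inherits(image, "zv_projection")) {
    if (image$bit_depth != 8) stop("otsu expects an 8-bit image")
    image$pixels
  } else image
  v <- as.integer(px)
  if (min(v) == max(v)) return(NA_integer_)
  hcount <- tabulate(v + 1L, nbins = 256L)
  n <- sum(hcount)
  levels <- 0:255
  w0 <- cumsum(hcount) / n                    # P(class0) for t = 0..255
  s0 <- cumsum(hcount * levels) / n           # unnormalised class-0 mean mass
  mu_t <- s0[256]
  w0 <- w0[1:255]; s0 <- s0[1:255]
  sigma_b <- (mu_t * w0 - s0)^2 / (w0 * (1 - w0))
  sigma_b[w0 <= 0 | w0 >= 1] <- -Inf
  as.integer(which.max(sigma_b) - 1L)         # which.max takes the first tie
}

#' Initial Otsu vessel mask
#'
#' Foreground = pixels strictly above the Otsu threshold. A constant image
#' yields an all-background mask with a warning.
#'
#' @inheritParams otsu_threshold
#' @return A `zv_mask`.
#' @export
otsu_mask <- function(image) {
  px <- if (inherits(image, "zv_projection")) image$pixels else image
  t <- otsu_threshold(image)
  if (is.na(t)) {
    warning("constant image: Otsu mask is empty")
    return(new_mask(px > Inf, "otsu"))
  }
  new_mask(px > t, "otsu")
}

#' Construct a vessel mask
#'
#' Wraps a logical pixel matrix with its processing provenance (ordered
#' stage names). Mostly produced by [otsu_mask()] and [refine_mask()];
#' exported so externally derived or ground-truth masks can enter the
#' metric pipeline.
#'
#' @param pixels Logical matrix.
#' @param stage Stage name appended to the provenance.
#' @param provenance Existing provenance to extend.
#' @return A `zv_mask`.
#' @export
new_mask <- function(pixels, stage, provenance = character(0)) {
  structure(list(pixels = pixels, provenance = c(provenance, stage)),
            class = "zv_mask")
}

#' @export
print.zv_mask <- function(x, ...) {
  cat(sprintf("<zv_mask> %d x %d px, %d foreground px, stages: %s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}
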