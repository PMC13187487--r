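# Reading calibrated z-stacks, maximum-intensity projection, channel
# handling and TIFF round-tripping.
#
# Axis convention throughout the package: stacks are (z, y, x) arrays,
# images are (y, x) matrices, origin top-left, 0-based pixel coordinates
# in all (y, x) coordinate lists.

# Acquisition defaults: the pipeline was developed for confocal stacks
# taken at 1.2 px/um in XY and a 5 um z-step; both are overridable.
DEFAULT_SCALE_PX_PER_UM <- 1.2
DEFAULT_Z_STEP_UM <- 5

#' Construct a calibrated z-stack
#'
#' @param voxels Numeric array, dims (z, y, x), or a (y, x) matrix for a
#'   single slice. Per-channel data: supply a list of such arrays via
#'   [split_channels()]-compatible `channel_names`.
#' @param pixel_size_um XY pixel size in micrometres (> 0).
#' @param z_step_um Axial step between slices in micrometres (> 0).
#' @param channel_names Character vector of channel labels. Multi-channel
#'   voxel data must be a 4D array (channel, z, y, x).
#' @param bit_depth 8 or 16.
#' @return A `zv_stack` object.
#' @export
calibrated_stack <- function(voxels, pixel_size_um = 1 / DEFAULT_SCALE_PX_PER_UM,
                             z_step_um = DEFAULT_Z_STEP_UM,
                             channel_names = "ch1", bit_depth = 16) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, nrow(voxels), ncol(voxels)))
  nd <- length(dim(voxels))
  if (length(channel_names) > 1L && nd == 3L)
    stop("multi-channel stacks need a 4D (channel, z, y, x) array")
  if (nd == 3L) voxels <- array(voxels, c(1L, dim(voxels)))
  if (length(dim(voxels)) != 4L) stop("voxels must have dims (z, y, x) or (channel, z, y, x)")
  if (dim(voxels)[1] != length(channel_names))
    stop("first dim must match length(channel_names)")
  if (dim(voxels)[2] < 1L) stop("stack has zero slices")
  if (pixel_size_um <= 0 || z_step_um <= 0) stop("calibration values must be > 0")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  structure(list(
    voxels = voxels,
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    n_slices = dim(voxels)[2],
    channel_names = as.character(channel_names),
    bit_depth = bit_depth
  ), class = "zv_stack")
}

#' @export
print.zv_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<zv_stack> %d channel(s) [%s], %d slice(s), %d x %d px, %.4g um/px, z-step %.4g um (depth %.4g um)\n",
    d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
    x$pixel_size_um, x$z_step_um, z_depth_um(x)))
  invisible(x)
}

#' Physical depth of a stack in micrometres
#' @param stack A `zv_stack`.
#' @export
z_depth_um <- function(stack) stack$n_slices * stack$z_step_um

#' Construct a 2D projection image
#'
#' @param pixels Numeric matrix (y, x) of integer intensities.
#' @param bit_depth 8 or 16.
#' @param pixel_size_um XY pixel size (um/px).
#' @param z_depth_um Depth of the source stack in um; 0 is only meaningful
#'   for images with no stack provenance and blocks depth-normalised metrics.
#' @param channel Channel label.
#' @export
projection_image <- function(pixels, bit_depth = 16,
                             pixel_size_um = 1 / DEFAULT_SCALE_PX_PER_UM,
                             z_depth_um = 0, channel = "ch1") {
  stopifnot(is.matrix(pixels))
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  mx <- 2^bit_depth - 1
  if (any(pixels < 0 | pixels > mx)) stop("pixel values outside [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 pixel_size_um = pixel_size_um, z_depth_um = z_depth_um,
                 channel = channel), class = "zv_projection")
}

#' @export
print.zv_projection <- function(x, ...) {
  cat(sprintf("<zv_projection> %d x %d px, %d-bit, %.4g um/px, z-depth %.4g um, channel %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$pixel_size_um,
              x$z_depth_um, x$channel))
  invisible(x)
}

#' Read a z-stack from disk
#'
#' Reads single- or multi-page grayscale TIFF files (8/16-bit). Pages are
#' z-slices; for `n_channels > 1` pages are de-interleaved channel-fastest
#' (c1z1, c2z1, c1z2, ...). Calibration precedence is explicit arguments >
#' embedded TIFF resolution tags > package defaults (1/1.2 um/px, 5 um
#' z-step); falling back to a default logs a warning. CZI is not a
#' supported input format of this implementation; convert to TIFF upstream.
#'
#' @param path Path to a TIFF file.
#' @param format_hint One of "auto", "tiff", "czi".
#' @param pixel_size_um,z_step_um Optional calibration overrides.
#' @param n_channels Number of interleaved channels in the file.
#' @param channel_names Optional channel labels.
#' @return A `zv_stack`.
#' @export
read_stack <- function(path, format_hint = c("auto", "tiff", "czi"),
                       pixel_size_um = NULL, z_step_um = NULL,
                       n_channels = 1L, channel_names = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("cannot read stack: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- if (format_hint == "auto") {
    if (ext == "czi") "czi" else "tiff"
  } else format_hint
  if (fmt == "czi")
    stop("CZI input is not supported by this implementation; ",
         "export the stack as multi-page TIFF and re-run: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("stack has zero slices: ", path)
  bps <- attr(pages[[1]], "bits.per.sample") %||% 16
  bit_depth <- if (isTRUE(bps <= 8)) 8 else 16
  # embedded XY resolution (pixels per unit) if present and interpretable
  meta_px_um <- NULL
  xres <- attr(pages[[1]], "x.resolution")
  runit <- attr(pages[[1]], "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(runit)) {
    per_um <- switch(as.character(runit),
                     "inch" = xres / 25400, "2" = xres / 25400,
                     "cm" = xres / 1e4, "3" = xres / 1e4, NULL)
    if (!is.null(per_um) && per_um > 0) meta_px_um <- 1 / per_um
  }
  if (is.null(pixel_size_um)) {
    if (!is.null(meta_px_um)) pixel_size_um <- meta_px_um
    else {
      pixel_size_um <- 1 / DEFAULT_SCALE_PX_PER_UM
      warning("pixel size missing from metadata/config; using default ",
              signif(pixel_size_um, 6), " um/px (1.2 px/um)")
    }
  } else if (!is.null(meta_px_um) && abs(meta_px_um - pixel_size_um) > 1e-9) {
    warning("config pixel size overrides embedded metadata (",
            signif(meta_px_um, 6), " um/px)")
  }
  if (is.null(z_step_um)) {
    z_step_um <- DEFAULT_Z_STEP_UM
    warning("z-step missing from metadata/config; using default ",
            z_step_um, " um")
  }
  to_int <- function(p) {
    if (is.array(p) && length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples
    m <- matrix(as.numeric(p), nrow(p), ncol(p))
    if (max(m) <= 1 && !isTRUE(bps > 1)) m <- round(m * (2^bit_depth - 1))
    m
  }
  slices <- lapply(pages, to_int)
  n_channels <- as.integer(n_channels)
  if (length(slices) %% n_channels != 0L)
    stop("page count ", length(slices), " not divisible by n_channels ", n_channels)
  nz <- length(slices) %/% n_channels
  h <- nrow(slices[[1]]); w <- ncol(slices[[1]])
  vox <- array(0, c(n_channels, nz, h, w))
  for (k in seq_along(slices)) {
    ch <- ((k - 1L) %% n_channels) + 1L
    z <- ((k - 1L) %/% n_channels) + 1L
    vox[ch, z, , ] <- slices[[k]]
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_channels))
  calibrated_stack(vox, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                   channel_names = channel_names, bit_depth = bit_depth)
}

#' Maximum-intensity projection of one channel
#'
#' Each output pixel is the maximum over z of the corresponding voxel
#' column; calibration and bit depth are carried over.
#'
#' @param stack A `zv_stack`.
#' @param channel Channel index (1-based) or name.
#' @return A `zv_projection`.
#' @export
max_project <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "zv_stack"))
  if (is.character(channel)) channel <- match(channel, stack$channel_names)
  if (is.na(channel) || channel < 1L || channel > length(stack$channel_names))
    stop("invalid channel index")
  nz <- stack$n_slices
  d <- dim(stack$voxels)
  proj <- matrix(stack$voxels[channel, 1, , ], d[3], d[4])
  if (nz > 1L) for (z in 2:nz)
    proj <- pmax(proj, matrix(stack$voxels[channel, z, , ], d[3], d[4]))
  projection_image(proj, bit_depth = stack$bit_depth,
                   pixel_size_um = stack$pixel_size_um,
                   z_depth_um = z_depth_um(stack),
                   channel = stack$channel_names[channel])
}

#' Split a multi-channel stack into single-channel stacks
#'
#' @param stack A `zv_stack`.
#' @return List of single-channel `zv_stack` objects, input order preserved.
#' @export
split_channels <- function(stack) {
  stopifnot(inherits(stack, "zv_stack"))
  lapply(seq_along(stack$channel_names), function(ch) {
    vox <- stack$voxels[ch, , , , drop = FALSE]
    dim(vox) <- dim(stack$voxels)[-1]
    calibrated_stack(vox, pixel_size_um = stack$pixel_size_um,
                     z_step_um = stack$z_step_um,
                     channel_names = stack$channel_names[ch],
                     bit_depth = stack$bit_depth)
  })
}

#' Write a projection (or mask/skeleton) to TIFF
#'
#' Projections keep their bit depth; logical masks are written 8-bit with
#' foreground 255.
#'
#' @param x A `zv_projection`, `zv_mask`, or matrix.
#' @param path Output path.
#' @export
write_image_tiff <- function(x, path) {
  if (inherits(x, "zv_projection")) {
    tiff::writeTIFF(x$pixels / (2^x$bit_depth - 1), path,
                    bits.per.sample = x$bit_depth, compression = "none")
  } else {
    m <- as_mask_matrix(x)
    tiff::writeTIFF((m * 255) / 255, path, bits.per.sample = 8,
                    compression = "none")
  }
  invisible(path)
}

#' Read a single 2D projection image from TIFF/PNG
#'
#' For images with no stack provenance `z_depth_um` must be supplied
#' explicitly when depth-normalised metrics are wanted.
#'
#' @inheritParams read_stack
#' @param z_depth_um Physical depth of the source stack (um); 0 = unknown.
#' @export
read_projection <- function(path, pixel_size_um = NULL, z_depth_um = 0,
                            channel = "ch1") {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    bit_depth <- 16
    m <- round(matrix(as.numeric(p), nrow(p), ncol(p)) * 65535)
  } else {
    p <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(p)) == 3L) p <- p[, , 1]
    bps <- attr(p, "bits.per.sample") %||% 16
    bit_depth <- if (isTRUE(bps <= 8)) 8 else 16
    m <- matrix(as.numeric(p), nrow(p), ncol(p))
  }
  if (is.null(pixel_size_um)) {
    pixel_size_um <- 1 / DEFAULT_SCALE_PX_PER_UM
    warning("pixel size not supplied; using default ",
            signif(pixel_size_um, 6), " um/px")
  }
  projection_image(m, bit_depth = bit_depth, pixel_size_um = pixel_size_um,
                   z_depth_um = z_depth_um, channel = channel)
}
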