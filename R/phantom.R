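# Synthetic vascular phantoms with exact ground truth. Geometry (analytic
# centrelines, widths, junction coordinates) is drawn first and recorded;
# rendering (stroke, PSF blur, background, noise) happens afterwards, so
# the truth is never contaminated by raster or thinning artefacts.

#' Phantom specification
#'
#' Defaults describe the study conditions used throughout the test suite:
#' a trunk-like ladder of intersegmental vessels (two longitudinal vessels
#' joined by evenly spaced rungs), vessel width 5 px, junction separations
#' of at least 40 px, bright vessels (level 200) on a dim background
#' (level 30, signal-to-background ratio ~6.7), 1 px PSF blur and mild
#' Gaussian noise (sd 4, about 2% of the rendered dynamic range).
#'
#' @param shape c(height, width) in pixels.
#' @param topology "grid_isv", "tree", "plus" or "bar".
#' @param n_branches Branch count (rungs for "grid_isv", bifurcations for
#'   "tree").
#' @param widths_px Vessel width(s) in pixels (recycled over branches).
#' @param min_junction_sep_px Minimum distance between junctions.
#' @param background "flat" or "gradient" (horizontal ramp 0.6-1.4x level).
#' @param background_level,vessel_level Intensity levels (0-255 scale;
#'   vessel_level must exceed background_level).
#' @param psf_sigma_px Gaussian blur sigma (0 = none).
#' @param noise_model "none", "gaussian" or "poisson".
#' @param noise_scale Gaussian sd, or Poisson exposure factor.
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @export
phantom_spec <- function(shape = c(260, 480),
                         topology = c("grid_isv", "tree", "plus", "bar"),
                         n_branches = 10L,
                         widths_px = 5,
                         min_junction_sep_px = 40,
                         background = c("flat", "gradient"),
                         background_level = 30,
                         vessel_level = 200,
                         psf_sigma_px = 1,
                         noise_model = c("gaussian", "none", "poisson"),
                         noise_scale = 4,
                         seed = 1L) {
  topology <- match.arg(topology)
  background <- match.arg(background)
  noise_model <- match.arg(noise_model)
  if (vessel_level <= background_level)
    stop("vessel_level must exceed background_level")
  if (any(widths_px < 1)) stop("widths must be >= 1 px")
  if (min_junction_sep_px <= 0) stop("min_junction_sep_px must be > 0")
  structure(list(shape = as.integer(shape), topology = topology,
                 n_branches = as.integer(n_branches), widths_px = widths_px,
                 min_junction_sep_px = min_junction_sep_px,
                 background = background,
                 background_level = background_level,
                 vessel_level = vessel_level,
                 psf_sigma_px = psf_sigma_px, noise_model = noise_model,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "zv_phantom_spec")
}

# integer Bresenham raster of a segment; returns 0-based (y, x) rows
bresenham <- function(y0, x0, y1, x1) {
  y0 <- round(y0); x0 <- round(x0); y1 <- round(y1); x1 <- round(x1)
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  n <- max(dy, dx)
  if (n == 0L) return(cbind(y = y0, x = x0))
  t <- seq(0, 1, length.out = n + 1)
  cbind(y = round(y0 + t * (y1 - y0)), x = round(x0 + t * (x1 - x0)))
}

# paint a flat-capped thick segment: pixels whose perpendicular distance to
# the segment's supporting line is <= (w-1)/2 with projection inside [0, 1]
paint_segment <- function(mask, y0, x0, y1, x1, width) {
  h <- nrow(mask); w_img <- ncol(mask)
  r <- (width - 1) / 2
  ylo <- max(0, floor(min(y0, y1) - r)); yhi <- min(h - 1, ceiling(max(y0, y1) + r))
  xlo <- max(0, floor(min(x0, x1) - r)); xhi <- min(w_img - 1, ceiling(max(x0, x1) + r))
  if (ylo > yhi || xlo > xhi) return(mask)
  ys <- ylo:yhi; xs <- xlo:xhi
  yy <- matrix(rep(ys, length(xs)), length(ys), length(xs))
  xx <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  vy <- y1 - y0; vx <- x1 - x0
  len2 <- vy^2 + vx^2
  if (len2 == 0) {
    inside <- (yy - y0)^2 + (xx - x0)^2 <= r^2
  } else {
    t <- ((yy - y0) * vy + (xx - x0) * vx) / len2
    perp2 <- (yy - y0 - t * vy)^2 + (xx - x0 - t * vx)^2
    # half-pixel axial slack so rounded (Bresenham) endpoints stay inside
    slack <- 0.5 / sqrt(len2)
    inside <- t >= -slack & t <= 1 + slack & perp2 <= r^2 + 1e-9
  }
  mask[ys + 1, xs + 1] <- mask[ys + 1, xs + 1] | inside
  mask
}

#' Ladder layout of trunk intersegmental vessels
#'
#' Two horizontal longitudinal vessels joined by `n_branches` evenly
#' spaced vertical rungs. Each rung contributes two junctions; rung
#' spacing must exceed `min_junction_sep_px`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `branches` (matrix y0,x0,y1,x1,width) and `junctions`
#'   ((y, x) matrix).
#' @export
grid_isv_layout <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  n <- spec$n_branches
  margin <- max(10, ceiling(max(spec$widths_px)))
  y_top <- round(h * 0.25); y_bot <- round(h * 0.75)
  if (y_bot - y_top < spec$min_junction_sep_px)
    stop("image too small: longitudinal vessels closer than junction separation")
  widths <- rep(spec$widths_px, length.out = n + 2)
  branches <- rbind(
    c(y_top, margin, y_top, w - 1 - margin, widths[n + 1]),
    c(y_bot, margin, y_bot, w - 1 - margin, widths[n + 2])
  )
  junctions <- NULL
  if (n > 0) {
    span <- (w - 1 - 2 * margin)
    if (n > 1 && span / (n - 1) <= spec$min_junction_sep_px)
      stop("image too small for requested rungs at this junction separation")
    xr <- if (n == 1) round(w / 2) else
      round(seq(margin + span * 0.05, w - 1 - margin - span * 0.05,
                length.out = n))
    branches <- rbind(branches,
                      cbind(y_top, xr, y_bot, xr, widths[seq_len(n)]))
    junctions <- rbind(cbind(y = rep(y_top, n), x = xr),
                       cbind(y = rep(y_bot, n), x = xr))
  }
  colnames(branches) <- c("y0", "x0", "y1", "x1", "width")
  list(branches = branches,
       junctions = junctions %||% matrix(numeric(0), ncol = 2,
                                         dimnames = list(NULL, c("y", "x"))))
}

plus_layout <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  cy <- round(h / 2); cx <- round(w / 2)
  arm <- min(cy, cx) - max(6, ceiling(max(spec$widths_px)))
  widths <- rep(spec$widths_px, length.out = 4)
  branches <- rbind(
    c(cy, cx, cy - arm, cx, widths[1]),
    c(cy, cx, cy + arm, cx, widths[2]),
    c(cy, cx, cy, cx - arm, widths[3]),
    c(cy, cx, cy, cx + arm, widths[4])
  )
  colnames(branches) <- c("y0", "x0", "y1", "x1", "width")
  list(branches = branches, junctions = cbind(y = cy, x = cx))
}

bar_layout <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  cy <- round(h / 2)
  margin <- max(6, ceiling(max(spec$widths_px)))
  branches <- matrix(c(cy, margin, cy, w - 1 - margin, spec$widths_px[1]),
                     1, 5, dimnames = list(NULL, c("y0", "x0", "y1", "x1", "width")))
  list(branches = branches,
       junctions = matrix(numeric(0), ncol = 2,
                          dimnames = list(NULL, c("y", "x"))))
}

# random binary tree grown from the bottom edge; junction separations are
# enforced with bounded retries
tree_layout <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  margin <- max(6, ceiling(max(spec$widths_px)))
  sep <- spec$min_junction_sep_px
  widths <- rep(spec$widths_px, length.out = 2 * spec$n_branches + 1)
  branches <- NULL; junctions <- NULL
  tips <- list(list(y = h - 1 - margin, x = round(w / 2), ang = -pi / 2))
  wi <- 1
  for (b in seq_len(max(spec$n_branches, 0))) {
    placed <- FALSE
    for (try in 1:50) {
      ti <- sample.int(length(tips), 1)
      tip <- tips[[ti]]
      len <- stats::runif(1, sep, sep * 1.6)
      ny <- tip$y + sin(tip$ang) * len
      nx <- tip$x + cos(tip$ang) * len
      if (ny < margin || ny > h - 1 - margin || nx < margin || nx > w - 1 - margin) next
      if (!is.null(junctions) &&
          any((junctions[, 1] - ny)^2 + (junctions[, 2] - nx)^2 < sep^2)) next
      branches <- rbind(branches, c(tip$y, tip$x, ny, nx, widths[wi])); wi <- wi + 1
      junctions <- rbind(junctions, cbind(y = round(ny), x = round(nx)))
      spread <- stats::runif(1, 0.35, 0.6)
      tips[[ti]] <- list(y = ny, x = nx, ang = tip$ang - spread)
      tips[[length(tips) + 1]] <- list(y = ny, x = nx, ang = tip$ang + spread)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place tree branches under the separation constraint")
  }
  # extend every open tip so junctions are genuine bifurcations
  for (tip in tips) {
    len <- sep * 0.8
    ny <- min(max(tip$y + sin(tip$ang) * len, margin), h - 1 - margin)
    nx <- min(max(tip$x + cos(tip$ang) * len, margin), w - 1 - margin)
    branches <- rbind(branches, c(tip$y, tip$x, ny, nx, widths[wi]))
    wi <- if (wi < length(widths)) wi + 1 else wi
  }
  colnames(branches) <- c("y0", "x0", "y1", "x1", "width")
  list(branches = branches,
       junctions = junctions %||% matrix(numeric(0), ncol = 2,
                                         dimnames = list(NULL, c("y", "x"))))
}

#' Generate a synthetic vascular phantom
#'
#' Geometry first (exact centrelines, widths and junctions recorded as
#' ground truth), then rendering: flat-capped strokes at `vessel_level`
#' over the background, Gaussian PSF blur, then noise. Bit-reproducible
#' for a given seed.
#'
#' @param spec A [phantom_spec()].
#' @return A `zv_phantom` with fields `image` (16-bit matrix),
#'   `true_mask`, `true_skeleton`, `junctions`, `total_centreline_px`,
#'   `per_branch` (tibble), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "zv_phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$shape[1]; w <- spec$shape[2]
    geom <- switch(spec$topology,
                   grid_isv = grid_isv_layout(spec),
                   plus = plus_layout(spec),
                   bar = bar_layout(spec),
                   tree = tree_layout(spec))
    br <- geom$branches
    mask <- matrix(FALSE, h, w)
    skel <- matrix(FALSE, h, w)
    per_branch <- vector("list", nrow(br))
    for (i in seq_len(nrow(br))) {
      mask <- paint_segment(mask, br[i, 1], br[i, 2], br[i, 3], br[i, 4], br[i, 5])
      pts <- bresenham(br[i, 1], br[i, 2], br[i, 3], br[i, 4])
      keep <- pts[, 1] >= 0 & pts[, 1] < h & pts[, 2] >= 0 & pts[, 2] < w
      pts <- pts[keep, , drop = FALSE]
      skel[yx_to_idx(pts, h)] <- TRUE
      per_branch[[i]] <- tibble::tibble(length_px = nrow(pts), width_px = br[i, 5])
    }
    canvas <- if (spec$background == "gradient") {
      matrix(rep(seq(0.6, 1.4, length.out = w) * spec$background_level,
                 each = h), h, w)
    } else matrix(spec$background_level, h, w)
    canvas[mask] <- spec$vessel_level
    img <- if (spec$psf_sigma_px > 0) gauss_blur(canvas, spec$psf_sigma_px) else canvas
    img <- switch(spec$noise_model,
      none = img,
      gaussian = img + stats::rnorm(length(img), 0, spec$noise_scale),
      poisson = {
        expo <- max(spec$noise_scale, 1e-6)
        matrix(stats::rpois(length(img), pmax(img, 0) * expo) / expo, h, w)
      })
    img <- matrix(pmin(pmax(round(img), 0), 65535), h, w)
    structure(list(image = img, true_mask = mask, true_skeleton = skel,
                   junctions = geom$junctions,
                   total_centreline_px = sum(skel),
                   per_branch = dplyr::bind_rows(per_branch),
                   spec = spec),
              class = "zv_phantom")
  })
}

#' @export
print.zv_phantom <- function(x, ...) {
  cat(sprintf("<zv_phantom> %s, %d x %d px, %d centreline px, %d junction(s)\n",
              x$spec$topology, nrow(x$image), ncol(x$image),
              x$total_centreline_px, nrow(x$junctions)))
  invisible(x)
}

#' Projection view of a phantom
#'
#' @param phantom A `zv_phantom`.
#' @param pixel_size_um,z_depth_um Calibration to attach.
#' @export
phantom_projection <- function(phantom, pixel_size_um = 1 / DEFAULT_SCALE_PX_PER_UM,
                               z_depth_um = 100) {
  projection_image(phantom$image, bit_depth = 16,
                   pixel_size_um = pixel_size_um, z_depth_um = z_depth_um,
                   channel = "phantom")
}

#' Wrap a phantom image into a synthetic z-stack
#'
#' Produces an `n_slices` stack whose maximum-intensity projection equals
#' the phantom image exactly (slice 1 carries the full signal; deeper
#' slices are attenuated copies).
#'
#' @param phantom A `zv_phantom`.
#' @param n_slices Number of slices.
#' @param z_step_um Slice spacing.
#' @param pixel_size_um XY calibration.
#' @export
phantom_stack <- function(phantom, n_slices = 20L, z_step_um = DEFAULT_Z_STEP_UM,
                          pixel_size_um = 1 / DEFAULT_SCALE_PX_PER_UM) {
  h <- nrow(phantom$image); w <- ncol(phantom$image)
  vox <- array(0, c(n_slices, h, w))
  vox[1, , ] <- phantom$image
  if (n_slices > 1L) {
    att <- seq(0.6, 0.2, length.out = n_slices - 1)
    for (z in 2:n_slices) vox[z, , ] <- floor(phantom$image * att[z - 1])
  }
  calibrated_stack(vox, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                   channel_names = "phantom", bit_depth = 16)
}
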