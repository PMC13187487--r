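# Region-of-interest analysis: named regions (e.g. midbrain vs hindbrain,
# left/right halves, trunk thirds) given as polygons, boxes or axis-aligned
# half-planes in 0-based (y, x) pixel coordinates.

#' Define a region of interest
#'
#' @param roi_id Region name.
#' @param kind "polygon", "box" or "half_plane".
#' @param vertices Polygon: matrix/list of (y, x) vertices (>= 3).
#' @param corners Box: numeric vector c(y0, x0, y1, x1), inclusive corners.
#' @param axis,value,side Half-plane: `axis` "x" or "y", split `value`, and
#'   `side` "less" (coordinate < value) or "geq" (coordinate >= value).
#' @export
roi_spec <- function(roi_id, kind = c("polygon", "box", "half_plane"),
                     vertices = NULL, corners = NULL,
                     axis = NULL, value = NULL, side = c("less", "geq")) {
  kind <- match.arg(kind)
  spec <- list(roi_id = roi_id, kind = kind)
  if (kind == "polygon") {
    if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
    vertices <- as.matrix(vertices)
    if (nrow(vertices) < 3L) stop("polygon needs >= 3 vertices")
    if (polygon_area(vertices) == 0) stop("degenerate polygon (zero area)")
    spec$vertices <- vertices
  } else if (kind == "box") {
    corners <- as.numeric(corners)
    if (length(corners) != 4L) stop("box needs c(y0, x0, y1, x1)")
    spec$corners <- c(pmin(corners[c(1, 2)], corners[c(3, 4)]),
                      pmax(corners[c(1, 2)], corners[c(3, 4)]))
  } else {
    if (!axis %in% c("x", "y")) stop("half_plane axis must be 'x' or 'y'")
    spec$axis <- axis; spec$value <- as.numeric(value)
    spec$side <- match.arg(side)
  }
  structure(spec, class = "zv_roi")
}

polygon_area <- function(v) {
  y <- v[, 1]; x <- v[, 2]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Rasterise an ROI to a binary region mask
#'
#' Pixel centres (integer (y, x), 0-based) are tested; polygons use the
#' even-odd rule with boundary pixels included.
#'
#' @param spec A [roi_spec()].
#' @param shape Image shape c(height, width).
#' @return Logical matrix.
#' @export
rasterize_roi <- function(spec, shape) {
  stopifnot(inherits(spec, "zv_roi"))
  h <- shape[1]; w <- shape[2]
  yy <- matrix(rep(0:(h - 1), w), h, w)
  xx <- matrix(rep(0:(w - 1), each = h), h, w)
  switch(spec$kind,
    box = {
      c0 <- spec$corners
      yy >= c0[1] & yy <= c0[3] & xx >= c0[2] & xx <= c0[4]
    },
    half_plane = {
      coord <- if (spec$axis == "x") xx else yy
      if (spec$side == "less") coord < spec$value else coord >= spec$value
    },
    polygon = {
      inside <- point_in_polygon(as.numeric(yy), as.numeric(xx), spec$vertices)
      matrix(inside, h, w)
    }
  )
}

# Even-odd crossing test, vectorised over query points, with points lying
# on an edge counted as inside (boundary included).
point_in_polygon <- function(py, px, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- rep(FALSE, length(py))
  on_edge <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1]; xi <- v[i, 2]; yj <- v[j, 1]; xj <- v[j, 2]
    # boundary test: collinear and within the edge's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_seg <- abs(cross) <= eps * (1 + abs(xj - xi) + abs(yj - yi)) &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps
    on_edge <- on_edge | on_seg
    # crossing test on the horizontal ray in +x
    crosses <- ((yi > py) != (yj > py))
    xint <- xi + (py - yi) / (yj - yi) * (xj - xi)
    inside <- xor(inside, crosses & !is.na(xint) & px < xint)
    j <- i
  }
  inside | on_edge
}

#' Read ROI definitions from JSON
#'
#' Schema: `{"rois": [{"roi_id": "...", "kind": "polygon", "vertices":
#' [[y, x], ...]}, ...]}`; boxes use `"corners": [y0, x0, y1, x1]` and
#' half-planes `"axis"`, `"value"`, `"side"`.
#'
#' @param path JSON file path.
#' @return List of `zv_roi` objects.
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j$rois, function(r) {
    roi_spec(roi_id = r$roi_id, kind = r$kind,
             vertices = if (!is.null(r$vertices))
               do.call(rbind, lapply(r$vertices, as.numeric)),
             corners = if (!is.null(r$corners)) as.numeric(r$corners),
             axis = r$axis, value = r$value, side = r$side %||% "less")
  })
}

#' Per-ROI metric analysis
#'
#' Intersects the refined vessel mask with the rasterised region, crops to
#' the region's bounding box, and recomputes skeletonisation and all
#' downstream metrics inside the region (so ROI boundaries cannot inject
#' branchpoint artefacts from a cropped skeleton). An empty intersection
#' yields all-zero metrics with a warning.
#'
#' @param mask Refined `zv_mask` of the whole image.
#' @param spec A [roi_spec()] (or NULL for the whole image).
#' @inheritParams compute_image_metrics
#' @return As [compute_image_metrics()].
#' @export
analyze_roi <- function(mask, spec, scale_px_per_um, z_depth_um,
                        image_id = "image",
                        skel_params = skeleton_params(),
                        mad_pars = mad_params(),
                        n_slices = NULL, normalise_by = "depth_um") {
  m <- as_mask_matrix(mask)
  if (is.null(spec)) {
    return(compute_image_metrics(new_mask(m, "full"), scale_px_per_um,
                                 z_depth_um, image_id = image_id,
                                 roi_id = "full", skel_params = skel_params,
                                 mad_pars = mad_pars, n_slices = n_slices,
                                 normalise_by = normalise_by))
  }
  region <- rasterize_roi(spec, dim(m))
  clipped <- m & region
  if (!any(region)) stop("ROI does not overlap the image")
  if (!any(clipped))
    warning("ROI '", spec$roi_id, "' contains no vessel pixels")
  # crop to the region bounding box so density tiling is region-local
  ys <- range(which(rowSums(region) > 0))
  xs <- range(which(colSums(region) > 0))
  sub <- clipped[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE]
  compute_image_metrics(new_mask(sub, paste0("roi:", spec$roi_id)),
                        scale_px_per_um, z_depth_um, image_id = image_id,
                        roi_id = spec$roi_id, skel_params = skel_params,
                        mad_pars = mad_pars, n_slices = n_slices,
                        normalise_by = normalise_by)
}
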