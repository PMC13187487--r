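# Refined vessel mask, connected-component labelling and scriptable
# curation. The refined mask is the thresholded multiscale ridge response
# combined with the Otsu mask, followed by morphological clean-up.

#' Refine the vessel mask
#'
#' Thresholds the ridge response (strictly greater than
#' `meijering_threshold` keeps), combines with the Otsu mask per
#' `combine_with_otsu`, removes 8-connected foreground components smaller
#' than `min_object_px`, and fills 4-connected background holes smaller
#' than `max_hole_px`.
#'
#' @param response Ridge response matrix in [0, 255] from
#'   [tubularity_filter()].
#' @param otsu A `zv_mask` from [otsu_mask()] (ignored for
#'   `combine_with_otsu = "meijering_only"`).
#' @param params A [segmentation_params()] object.
#' @return A `zv_mask` with provenance.
#' @export
refine_mask <- function(response, otsu, params = segmentation_params()) {
  thr <- response > params$meijering_threshold
  stages <- c(paste0(params$filter_name, ">", params$meijering_threshold))
  m <- switch(params$combine_with_otsu,
    intersection = {
      om <- as_mask_matrix(otsu)
      if (!all(dim(om) == dim(thr))) stop("response/otsu shape mismatch")
      stages <- c(stages, "and_otsu"); thr & om
    },
    union = {
      om <- as_mask_matrix(otsu)
      if (!all(dim(om) == dim(thr))) stop("response/otsu shape mismatch")
      stages <- c(stages, "or_otsu"); thr | om
    },
    meijering_only = thr
  )
  m <- remove_small_objects(m, params$min_object_px)
  m <- fill_small_holes(m, params$max_hole_px)
  new_mask(m, "refine",
           provenance = c("otsu"[params$combine_with_otsu != "meijering_only"],
                          stages,
                          sprintf("rm_small<%d", params$min_object_px),
                          sprintf("fill_holes<%d", params$max_hole_px)))
}

#' Label vessel segments
#'
#' 8-connected components of the refined mask labelled 1..n in raster
#' order of each component's first pixel; deterministic.
#'
#' @param mask A `zv_mask` or logical matrix.
#' @return A `zv_labelmap`.
#' @export
label_segments <- function(mask) {
  lab <- label_components(as_mask_matrix(mask), 8)
  new_labelmap(lab, removed_ids = integer(0))
}

new_labelmap <- function(labels, removed_ids = integer(0)) {
  structure(list(labels = labels, n_segments = max(labels),
                 removed_ids = as.integer(removed_ids)),
            class = "zv_labelmap")
}

#' @export
print.zv_labelmap <- function(x, ...) {
  cat(sprintf("<zv_labelmap> %d x %d px, %d segment(s), %d removed\n",
              nrow(x$labels), ncol(x$labels), x$n_segments,
              length(x$removed_ids)))
  invisible(x)
}

#' Curate a label map
#'
#' Scriptable replacement for interactive mask curation: zeroes out the
#' listed segment IDs and (optionally) all segments below a pixel-size
#' bound, then relabels the survivors contiguously 1..m in raster order.
#' Unknown IDs are ignored with a warning. Removal decisions are recorded
#' in `removed_ids` so a curation session is a reproducible artefact.
#'
#' @param labelmap A `zv_labelmap`.
#' @param remove_ids Integer vector of segment IDs to remove.
#' @param min_segment_px Optional minimum surviving segment area.
#' @return A relabelled `zv_labelmap`.
#' @export
curate <- function(labelmap, remove_ids = integer(0), min_segment_px = NULL) {
  stopifnot(inherits(labelmap, "zv_labelmap"))
  lab <- labelmap$labels
  existing <- seq_len(labelmap$n_segments)
  remove_ids <- as.integer(remove_ids)
  unknown <- setdiff(remove_ids, existing)
  if (length(unknown))
    warning("ignoring unknown segment IDs: ", paste(unknown, collapse = ", "))
  remove_ids <- intersect(remove_ids, existing)
  if (!is.null(min_segment_px)) {
    sz <- component_sizes(lab)
    remove_ids <- union(remove_ids, which(sz < min_segment_px))
  }
  if (length(remove_ids)) lab[lab %in% remove_ids] <- 0L
  lab <- relabel_raster(lab)
  new_labelmap(lab, removed_ids = sort(union(labelmap$removed_ids, remove_ids)))
}

#' Mask of a label map's surviving segments
#' @param labelmap A `zv_labelmap`.
#' @export
labelmap_mask <- function(labelmap) {
  new_mask(labelmap$labels > 0L, "labelled")
}

#' Pseudo-colour rendering of a label map
#'
#' Deterministic label-to-colour mapping (golden-ratio hue walk), black
#' background. The same label map always renders identically.
#'
#' @param labelmap A `zv_labelmap`.
#' @return Numeric array (y, x, 3) with values in [0, 1].
#' @export
render_pseudocolour <- function(labelmap) {
  stopifnot(inherits(labelmap, "zv_labelmap"))
  lab <- labelmap$labels
  n <- labelmap$n_segments
  h <- nrow(lab); w <- ncol(lab)
  out <- array(0, c(h, w, 3))
  if (n == 0L) return(out)
  hues <- (0.12 + seq_len(n) * (sqrt(5) - 1) / 2) %% 1
  cols <- grDevices::hsv(hues, s = 0.75, v = 1)
  rgb <- grDevices::col2rgb(cols) / 255
  idx <- which(lab > 0L)
  labs <- lab[idx]
  for (k in 1:3) {
    plane <- matrix(0, h, w)
    plane[idx] <- rgb[k, labs]
    out[, , k] <- plane
  }
  out
}

#' Write a pseudo-colour rendering to PNG
#' @param labelmap A `zv_labelmap`.
#' @param path Output path.
#' @export
write_pseudocolour_png <- function(labelmap, path) {
  png::writePNG(render_pseudocolour(labelmap), path)
  invisible(path)
}
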