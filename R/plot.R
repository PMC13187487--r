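# ggplot2 views of result tables.

#' Plot benchmark grid results
#'
#' Bar chart of Q-score and Jaccard per filter x thinning-method cell.
#'
#' @param results Tibble from [run_grid()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  df <- tibble::tibble(
    combo = rep(paste(results$filter_name, results$skeleton_method, sep = " / "), 2),
    metric = rep(c("q_score", "jaccard"), each = nrow(results)),
    value = c(results$q_score, results$jaccard)
  )
  df$combo <- factor(df$combo, levels = unique(df$combo))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combo, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Segmentation / skeletonisation benchmark") +
    ggplot2::theme_minimal()
}

#' Histogram of per-segment diameters
#'
#' @param segments Per-segment tibble from [compute_image_metrics()] or
#'   [run_pipeline()]; MAD-excluded segments are shown in a separate fill.
#' @param binwidth Histogram bin width in pixels.
#' @return A ggplot object.
#' @export
plot_diameter_distribution <- function(segments, binwidth = 0.5) {
  df <- segments
  if (!"mad_excluded" %in% names(df)) df$mad_excluded <- FALSE
  df$status <- ifelse(df$mad_excluded, "excluded (MAD)", "retained")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diameter_px,
                                   fill = .data$status)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "segment mean diameter (px)", y = "segments") +
    ggplot2::theme_minimal()
}

#' Skeleton overlay for visual inspection
#'
#' Renders mask (grey), skeleton (white) and filtered branchpoints (red
#' squares) as an RGB array; write with [png::writePNG()].
#'
#' @param mask Vessel mask.
#' @param skel A `zv_skeleton` with branchpoints.
#' @param marker_px Half-size of the branchpoint marker.
#' @return Numeric array (y, x, 3) in [0, 1].
#' @export
render_overlay <- function(mask, skel, marker_px = 2) {
  m <- as_mask_matrix(mask)
  s <- skel$skeleton
  h <- nrow(m); w <- ncol(m)
  out <- array(0, c(h, w, 3))
  for (k in 1:3) out[, , k] <- m * 0.35 + s * 0.65
  bp <- skel$branchpoints_filtered
  if (!is.null(bp) && nrow(bp) > 0L) {
    for (i in seq_len(nrow(bp))) {
      ys <- max(1, bp[i, 1] + 1 - marker_px):min(h, bp[i, 1] + 1 + marker_px)
      xs <- max(1, bp[i, 2] + 1 - marker_px):min(w, bp[i, 2] + 1 + marker_px)
      out[ys, xs, 1] <- 1; out[ys, xs, 2] <- 0; out[ys, xs, 3] <- 0
    }
  }
  out
}
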