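# Physical-unit conversion, z-depth normalisation, asymmetric MAD outlier
# filtering and result export.

#' MAD outlier-filter parameters
#'
#' Asymmetric bounds around the median in raw MAD units: the default keeps
#' values in [median - 1*MAD, median + 3*MAD]. MAD here is the raw median
#' absolute deviation (no 1.4826 normal-consistency factor); set
#' `consistency = TRUE` to scale the MAD by 1.4826.
#'
#' @param lower_mult Lower bound multiplier (default 1).
#' @param upper_mult Upper bound multiplier (default 3).
#' @param targets Which per-segment distributions are filtered: subset of
#'   c("diameter", "length").
#' @param consistency Apply the 1.4826 normal-consistency factor (default
#'   FALSE).
#' @export
mad_params <- function(lower_mult = 1, upper_mult = 3,
                       targets = c("diameter", "length"),
                       consistency = FALSE) {
  if (lower_mult <= 0 || upper_mult <= 0) stop("MAD multipliers must be > 0")
  targets <- match.arg(targets, several.ok = TRUE)
  structure(list(lower_mult = lower_mult, upper_mult = upper_mult,
                 targets = targets, consistency = isTRUE(consistency)),
            class = "zv_mad_params")
}

#' Asymmetric MAD outlier filter
#'
#' Computes m = median(values) and mad = median(|values - m|), then retains
#' values inside the closed interval
#' [m - lower_mult * mad, m + upper_mult * mad]. With mad = 0 only values
#' equal to the median survive. Bound ties are retained (closed interval),
#' and the filter is scale-equivariant.
#'
#' @param values Numeric vector (length >= 1).
#' @param params A [mad_params()] object.
#' @return List with `retained` (subset of `values`, input order), `bounds`
#'   (length-2 numeric), and `keep` (logical mask over the input).
#' @export
mad_filter <- function(values, params = mad_params()) {
  if (length(values) == 0L) stop("mad_filter needs at least one value")
  m <- stats::median(values)
  mad <- stats::median(abs(values - m))
  if (params$consistency) mad <- mad * 1.4826
  bounds <- c(m - params$lower_mult * mad, m + params$upper_mult * mad)
  keep <- values >= bounds[1] & values <= bounds[2]
  list(retained = values[keep], bounds = bounds, keep = keep)
}

#' Convert a pixel-space metrics record to physical units
#'
#' Lengths and diameters are divided by the pixel-per-micron scale;
#' densities are converted to per-um^2 with scale^2; the normalised network
#' length divides the micron length by the physical z-depth of the source
#' stack (set `normalise_by = "slices"` to divide by slice count instead).
#'
#' @param record One-row tibble of pixel-space metrics (see
#'   [network_metrics()]).
#' @param scale_px_per_um Pixels per micrometre (> 0); the pipeline default
#'   is 1.2 px/um.
#' @param z_depth_um Physical depth of the source stack in um (> 0).
#' @param n_slices Optional slice count (needed for
#'   `normalise_by = "slices"`).
#' @param normalise_by "depth_um" (default) or "slices".
#' @return The record with micron-space columns added.
#' @export
to_physical_units <- function(record, scale_px_per_um, z_depth_um,
                              n_slices = NULL,
                              normalise_by = c("depth_um", "slices")) {
  normalise_by <- match.arg(normalise_by)
  if (scale_px_per_um <= 0) stop("scale_px_per_um must be > 0")
  if (z_depth_um <= 0) stop("z_depth_um must be > 0")
  denom <- if (normalise_by == "slices") {
    if (is.null(n_slices) || n_slices <= 0)
      stop("n_slices required for slice-count normalisation")
    n_slices
  } else z_depth_um
  area_um2 <- record$image_height_px * record$image_width_px / scale_px_per_um^2
  record$scale_px_per_um <- scale_px_per_um
  record$z_depth_um <- z_depth_um
  record$network_length_um <- record$network_length_px / scale_px_per_um
  record$normalised_network_length <- record$network_length_um / denom
  record$mean_diameter_um <- record$mean_diameter_px / scale_px_per_um
  record$branchpoint_density_per_um2 <- record$branchpoint_count / area_um2
  record
}

#' Full per-image metric extraction from a refined mask
#'
#' Runs skeletonisation, branchpoint detection and de-clustering, segment
#' decomposition, diameter estimation, pixel-space network metrics, MAD
#' filtering of the per-segment diameter and length distributions, and
#' physical-unit conversion. MAD filtering affects the per-segment summary
#' statistics (and segment exclusion flags); the total network length is
#' not recomputed from the filtered set.
#'
#' @param mask A `zv_mask` (refined/curated vessel mask).
#' @param scale_px_per_um Pixels per micrometre.
#' @param z_depth_um Physical z-depth (um) for normalisation.
#' @param image_id,roi_id Identifiers recorded in the output.
#' @param skel_params,mad_pars Parameter objects.
#' @param n_slices Optional slice count.
#' @param normalise_by See [to_physical_units()].
#' @return List with `record` (one-row tibble), `segments` (per-segment
#'   tibble with MAD flags) and `graph` (the `zv_skeleton`).
#' @export
compute_image_metrics <- function(mask, scale_px_per_um, z_depth_um,
                                  image_id = "image", roi_id = "full",
                                  skel_params = skeleton_params(),
                                  mad_pars = mad_params(),
                                  n_slices = NULL,
                                  normalise_by = "depth_um") {
  sg <- skeletonize(mask, skel_params)
  sg <- detect_branchpoints(sg, skel_params)
  sg <- filter_branchpoints(sg, skel_params)
  segs <- decompose_segments(sg)
  segs <- estimate_diameters(mask, segs)
  rec <- network_metrics(sg, segs, mask, scale_px_per_um, skel_params)

  n_pre <- nrow(segs)
  if (n_pre > 0L) {
    keep <- rep(TRUE, n_pre)
    if ("diameter" %in% mad_pars$targets)
      keep <- keep & mad_filter(segs$mean_diameter_px, mad_pars)$keep
    if ("length" %in% mad_pars$targets)
      keep <- keep & mad_filter(segs$length_px, mad_pars)$keep
    segs$mad_excluded <- !keep
  } else {
    segs$mad_excluded <- logical(0)
    keep <- logical(0)
  }
  post <- segs[!segs$mad_excluded, , drop = FALSE]
  rec$mean_diameter_px_pre_mad <- rec$mean_diameter_px
  rec$mean_diameter_px <- if (nrow(post) > 0L) {
    if (skel_params$mean_diameter_over == "pixels")
      mean(unlist(post$diameters_px)) else mean(post$mean_diameter_px)
  } else 0
  rec$mean_segment_length_px <- if (nrow(post) > 0L) mean(post$length_px) else 0
  rec$n_segments_pre_mad <- n_pre
  rec$n_segments_post_mad <- nrow(post)

  rec <- to_physical_units(rec, scale_px_per_um, z_depth_um,
                           n_slices = n_slices, normalise_by = normalise_by)
  rec <- tibble::add_column(rec, image_id = image_id, roi_id = roi_id,
                            skeleton_method = skel_params$method,
                            .before = 1)
  segs$image_id <- image_id
  segs$roi_id <- roi_id
  list(record = rec, segments = segs, graph = sg)
}

#' Export metric records and per-segment tables
#'
#' Writes a summary table (one row per image x ROI), one per-segment CSV
#' per image (with MAD exclusion flags), and a JSON provenance sidecar.
#' Re-exporting identical records is byte-identical.
#'
#' @param records Tibble of metric records (rows from
#'   [compute_image_metrics()]).
#' @param segment_tables Optional named list (or single tibble) of
#'   per-segment tables.
#' @param path Output directory (created if needed).
#' @param provenance Optional list of run parameters to record.
#' @return Invisible character vector of files written.
#' @export
export_results <- function(records, segment_tables = NULL, path,
                           provenance = NULL) {
  if (nrow(records) == 0L) stop("no records to export")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  files <- character(0)
  f <- file.path(path, "summary.csv")
  utils::write.csv(records, f, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(segment_tables)) {
    if (is.data.frame(segment_tables)) {
      segment_tables <- split(segment_tables, segment_tables$image_id)
    }
    for (nm in names(segment_tables)) {
      st <- segment_tables[[nm]]
      st <- st[, setdiff(names(st), c("pixel_coords", "diameters_px")),
               drop = FALSE]
      fs <- file.path(path, paste0("segments_", gsub("[^A-Za-z0-9_.-]", "_", nm),
                                   ".csv"))
      utils::write.csv(st, fs, row.names = FALSE)
      files <- c(files, fs)
    }
  }
  if (!is.null(provenance)) {
    fp <- file.path(path, "provenance.json")
    jsonlite::write_json(provenance, fp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <- c(files, fp)
  }
  invisible(files)
}
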