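# End-to-end orchestration: read -> project -> per-channel preprocessing,
# segmentation, curation, (per-ROI) skeleton analysis, unit conversion,
# MAD filtering and export, with full provenance.

#' Build a pipeline run configuration
#'
#' @param input Path(s) to TIFF stacks, or `zv_stack` / `zv_projection`
#'   objects (a single object or a list).
#' @param output_dir Directory for results and intermediates (NULL = no
#'   files written).
#' @param channels Channel indices/names to analyse (NULL = all).
#' @param pixel_size_um,z_step_um,z_depth_um Calibration overrides.
#' @param pre_params,seg_params,skel_params,mad_pars Module parameters.
#' @param rois List of [roi_spec()] (or path to an ROI JSON file); the
#'   whole image is always analysed as roi_id "full".
#' @param curation_ids Integer IDs to remove after labelling, or path to a
#'   curation JSON `{"removed_ids": [...], "min_segment_px": N}`.
#' @param min_segment_px Optional size-based segment exclusion.
#' @param save_intermediates Write per-stage TIFF/PNG artefacts.
#' @param normalise_by "depth_um" or "slices".
#' @param seed RNG seed recorded in provenance.
#' @export
run_config <- function(input, output_dir = NULL, channels = NULL,
                       pixel_size_um = NULL, z_step_um = NULL,
                       z_depth_um = NULL,
                       pre_params = preprocess_params(),
                       seg_params = segmentation_params(),
                       skel_params = skeleton_params(),
                       mad_pars = mad_params(),
                       rois = NULL, curation_ids = integer(0),
                       min_segment_px = NULL,
                       save_intermediates = FALSE,
                       normalise_by = "depth_um", seed = 1L) {
  structure(list(input = input, output_dir = output_dir, channels = channels,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 z_depth_um = z_depth_um,
                 pre_params = pre_params, seg_params = seg_params,
                 skel_params = skel_params, mad_pars = mad_pars,
                 rois = rois, curation_ids = curation_ids,
                 min_segment_px = min_segment_px,
                 save_intermediates = isTRUE(save_intermediates),
                 normalise_by = normalise_by, seed = as.integer(seed)),
            class = "zv_config")
}

#' Segment one projection (preprocess + tubularity + refinement + labels)
#'
#' Stage order: 8-bit normalisation, CLAHE, Otsu masking, multiscale
#' tubularity filtering, mask refinement, connected-component labelling,
#' scripted curation.
#'
#' @param projection A `zv_projection`.
#' @param pre_params,seg_params Parameter objects.
#' @param curation_ids,min_segment_px Curation inputs.
#' @return List with `enhanced`, `otsu`, `response`, `refined`, `labels`
#'   (curated `zv_labelmap`), and `mask` (curated vessel mask).
#' @export
segment_projection <- function(projection,
                               pre_params = preprocess_params(),
                               seg_params = segmentation_params(),
                               curation_ids = integer(0),
                               min_segment_px = NULL) {
  img8 <- normalize_to_8bit(projection)
  enh <- apply_clahe(img8, pre_params)
  om <- suppressWarnings(otsu_mask(enh))
  resp <- tubularity_filter(enh, seg_params)
  refined <- refine_mask(resp, om, seg_params)
  labels <- label_segments(refined)
  labels <- curate(labels, remove_ids = curation_ids,
                   min_segment_px = min_segment_px)
  mask <- labelmap_mask(labels)
  mask$provenance <- c(refined$provenance, "curate")
  list(enhanced = enh, otsu = om, response = resp, refined = refined,
       labels = labels, mask = mask)
}

#' Run the full quantification pipeline
#'
#' Processes every input image and channel independently through
#' segmentation, curation, and (per ROI, plus the whole image) skeleton
#' analysis, unit conversion, depth normalisation and MAD filtering.
#' Per-image failures in batch mode are logged as warnings and skipped.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `records` (tibble, one row per image x
#'   channel x ROI), `segments` (per-segment tibble) and `files` written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "zv_config"))
  inputs <- config$input
  if (!is.list(inputs) || inherits(inputs, c("zv_stack", "zv_projection")))
    inputs <- list(inputs)
  rois <- config$rois
  if (is.character(rois)) rois <- read_roi_json(rois)
  curation_ids <- config$curation_ids
  min_segment_px <- config$min_segment_px
  if (is.character(curation_ids)) {
    cj <- jsonlite::read_json(curation_ids, simplifyVector = TRUE)
    min_segment_px <- min_segment_px %||% cj$min_segment_px
    curation_ids <- as.integer(cj$removed_ids %||% integer(0))
  }
  all_records <- list(); all_segments <- list(); files <- character(0)
  out <- config$output_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  for (ii in seq_along(inputs)) {
    res <- tryCatch({
      x <- inputs[[ii]]
      image_base <- if (is.character(x))
        tools::file_path_sans_ext(basename(x)) else sprintf("image%02d", ii)
      projections <- pipeline_projections(x, config)
      recs <- list(); segs <- list()
      for (pj in projections) {
        image_id <- paste0(image_base, "_", pj$channel)
        zd <- config$z_depth_um %||% pj$z_depth_um
        if (zd <= 0)
          stop("z_depth_um unknown for '", image_id,
               "': supply it in run_config() (stage: metrics)")
        seg <- segment_projection(pj, config$pre_params, config$seg_params,
                                  curation_ids, min_segment_px)
        if (!is.null(out) && config$save_intermediates) {
          write_image_tiff(seg$enhanced, file.path(out, paste0(image_id, "_clahe.tif")))
          write_image_tiff(seg$refined, file.path(out, paste0(image_id, "_mask.tif")))
          write_pseudocolour_png(seg$labels, file.path(out, paste0(image_id, "_labels.png")))
        }
        scale <- 1 / pj$pixel_size_um
        region_specs <- c(list(NULL), rois)
        for (rs in region_specs) {
          mr <- analyze_roi(seg$mask, rs, scale_px_per_um = scale,
                            z_depth_um = zd, image_id = image_id,
                            skel_params = config$skel_params,
                            mad_pars = config$mad_pars,
                            normalise_by = config$normalise_by)
          recs[[length(recs) + 1]] <- mr$record
          segs[[length(segs) + 1]] <- mr$segments
        }
      }
      list(recs = recs, segs = segs)
    }, error = function(e) {
      warning("skipping input ", ii, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      all_records <- c(all_records, res$recs)
      all_segments <- c(all_segments, res$segs)
    }
  }
  if (length(all_records) == 0L) stop("pipeline produced no results")
  records <- dplyr::bind_rows(all_records)
  segments <- dplyr::bind_rows(all_segments)
  if (!is.null(out)) {
    prov <- list(package_version = as.character(utils::packageVersion("zebravasc")),
                 seed = config$seed,
                 curation_ids = curation_ids,
                 min_segment_px = min_segment_px,
                 pre_params = unclass(config$pre_params),
                 seg_params = unclass(config$seg_params),
                 skel_params = unclass(config$skel_params),
                 mad_params = unclass(config$mad_pars),
                 normalise_by = config$normalise_by)
    files <- export_results(records, segments, out, provenance = prov)
  }
  invisible(list(records = records, segments = segments, files = files))
}

# resolve one input into per-channel projections
pipeline_projections <- function(x, config) {
  if (is.character(x)) {
    x <- read_stack(x, pixel_size_um = config$pixel_size_um,
                    z_step_um = config$z_step_um)
  }
  if (inherits(x, "zv_projection")) {
    if (!is.null(config$pixel_size_um)) x$pixel_size_um <- config$pixel_size_um
    return(list(x))
  }
  stopifnot(inherits(x, "zv_stack"))
  if (!is.null(config$pixel_size_um)) x$pixel_size_um <- config$pixel_size_um
  if (!is.null(config$z_step_um)) x$z_step_um <- config$z_step_um
  chans <- config$channels %||% seq_along(x$channel_names)
  lapply(chans, function(ch) max_project(x, ch))
}
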