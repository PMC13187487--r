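# Segmentation and skeletonisation benchmarking: Jaccard overlap against a
# reference mask, the connectivity x length x area Q-score against a
# reference skeleton, and the filter x thinning-method selection grid.

#' Jaccard similarity of two binary masks
#'
#' |A intersect B| / |A union B|. Two empty masks are identical sets, so
#' the index is defined as 1 with a warning.
#'
#' @param mask_a,mask_b Logical matrices (or `zv_mask`) of equal shape.
#' @return Numeric in [0, 1].
#' @export
jaccard <- function(mask_a, mask_b) {
  a <- as_mask_matrix(mask_a); b <- as_mask_matrix(mask_b)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  uni <- sum(a | b)
  if (uni == 0L) {
    warning("both masks empty: Jaccard defined as 1")
    return(1)
  }
  sum(a & b) / uni
}

#' Skeleton quality Q-score
#'
#' Q = connectivity x length x area, each factor in [0, 1]:
#' connectivity penalises the difference in 8-connected component counts
#' relative to the reference pixel count; length is the fraction of
#' candidate pixels within `tolerance_px` of the reference; area is the
#' fraction of reference pixels within `tolerance_px` of the candidate.
#' An identical candidate scores 1 in all three factors.
#'
#' @param skel Candidate skeleton (logical matrix or `zv_skeleton`).
#' @param ref Reference skeleton (non-empty).
#' @param tolerance_px Match tolerance in pixels (default 2).
#' @return One-row tibble with `q_connectivity`, `q_length`, `q_area`,
#'   `q_score`.
#' @export
q_score <- function(skel, ref, tolerance_px = 2) {
  s <- as_mask_matrix(skel); r <- as_mask_matrix(ref)
  if (!all(dim(s) == dim(r))) stop("skeleton shapes differ")
  n_ref <- sum(r)
  if (n_ref == 0L) stop("reference skeleton is empty")
  cc_s <- max(label_components(s, 8))
  cc_r <- max(label_components(r, 8))
  q_conn <- 1 - min(1, abs(cc_s - cc_r) / n_ref)
  if (!any(s)) {
    q_len <- 0; q_area <- 0
  } else {
    dref <- dist_to_set(r)
    q_len <- mean(dref[s] <= tolerance_px)
    dcand <- dist_to_set(s)
    q_area <- mean(dcand[r] <= tolerance_px)
  }
  tibble::tibble(q_connectivity = q_conn, q_length = q_len, q_area = q_area,
                 q_score = q_conn * q_len * q_area)
}

#' Run the filter x skeletonisation selection grid
#'
#' Evaluates every combination of tubularity filter and thinning method on
#' one image: shared pre-processing (8-bit normalisation, CLAHE, Otsu),
#' per-filter mask refinement scored by Jaccard against the reference
#' mask, and per-method skeletons scored by Q-score against the reference
#' skeleton. Results are sorted by Q-score then Jaccard, descending, with
#' name order as the deterministic tie-break.
#'
#' @param image A `zv_projection`.
#' @param reference_mask Reference vessel mask.
#' @param reference_skeleton Reference centreline (non-empty).
#' @param filters Character vector of filter names.
#' @param methods Character vector of thinning methods.
#' @param seg_params Base [segmentation_params()] (filter name is swept).
#' @param pre_params [preprocess_params()].
#' @param tolerance_px Q-score tolerance.
#' @return Tibble, one row per grid cell.
#' @export
run_grid <- function(image, reference_mask, reference_skeleton,
                     filters = c("meijering", "frangi", "sato", "jerman"),
                     methods = c("lee", "zhang"),
                     seg_params = segmentation_params(),
                     pre_params = preprocess_params(),
                     tolerance_px = 2) {
  ref_m <- as_mask_matrix(reference_mask)
  ref_s <- as_mask_matrix(reference_skeleton)
  img8 <- normalize_to_8bit(image)
  enh <- apply_clahe(img8, pre_params)
  om <- suppressWarnings(otsu_mask(enh))
  rows <- list()
  for (f in filters) {
    sp <- seg_params; sp$filter_name <- f
    resp <- tubularity_filter(enh, sp)
    refined <- refine_mask(resp, om, sp)
    jac <- jaccard(refined, ref_m)
    for (meth in methods) {
      sk <- skeletonize(refined, skeleton_params(method = meth))
      qs <- q_score(sk, ref_s, tolerance_px)
      rows[[paste(f, meth)]] <- tibble::tibble(
        filter_name = f, skeleton_method = meth, jaccard = jac, qs)
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(-out$q_score, -out$jaccard, out$filter_name, out$skeleton_method), ]
}
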