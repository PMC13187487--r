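# Skeletonisation and centreline analysis: topology-preserving thinning,
# branchpoint/endpoint detection, distance-based branchpoint de-clustering,
# segment decomposition and inscribed-circle diameter estimation.

#' Skeleton-analysis parameters
#'
#' @param min_branch_dist_px Minimum Euclidean distance between retained
#'   branchpoints (default 30, roughly the mean vessel segment length).
#' @param method Thinning variant: "lee" (default) or "zhang".
#' @param density_tile_um2 Tile area for vessel density, in square
#'   micrometres (default 100, i.e. 10 um x 10 um windows).
#' @param branch_rule "inclusive" (default) flags skeleton pixels with >= 3
#'   skeleton neighbours in the 3x3 window, catching simple T/Y
#'   bifurcations; "strict" requires >= 4.
#' @param mean_diameter_over "segments" (default) averages segment mean
#'   diameters; "pixels" averages over all skeleton pixels.
#' @export
skeleton_params <- function(min_branch_dist_px = 30,
                            method = c("lee", "zhang"),
                            density_tile_um2 = 100,
                            branch_rule = c("inclusive", "strict"),
                            mean_diameter_over = c("segments", "pixels")) {
  method <- match.arg(method)
  branch_rule <- match.arg(branch_rule)
  mean_diameter_over <- match.arg(mean_diameter_over)
  if (min_branch_dist_px <= 0) stop("min_branch_dist_px must be > 0")
  if (density_tile_um2 <= 0) stop("density_tile_um2 must be > 0")
  structure(list(min_branch_dist_px = min_branch_dist_px, method = method,
                 density_tile_um2 = density_tile_um2,
                 branch_rule = branch_rule,
                 mean_diameter_over = mean_diameter_over),
            class = "zv_skeleton_params")
}

# value of the neighbour at offset (oy, ox): out[y, x] = m[y + oy, x + ox]
nb_at <- function(m, oy, ox) shift_mat(m, -oy, -ox, 0)

# ---- Zhang-Suen thinning (two-subiteration parallel deletion) ------------

thin_zhang <- function(m) {
  m <- m * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # P2..P9 clockwise from north
      P <- list(nb_at(m, -1, 0), nb_at(m, -1, 1), nb_at(m, 0, 1),
                nb_at(m, 1, 1), nb_at(m, 1, 0), nb_at(m, 1, -1),
                nb_at(m, 0, -1), nb_at(m, -1, -1))
      B <- Reduce(`+`, P)
      A <- matrix(0, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        A <- A + (P[[i]] == 0) * (P[[j]] == 1)
      }
      cond <- m == 1 & B >= 2 & B <= 6 & A == 1
      if (step == 1) {
        cond <- cond & (P[[1]] * P[[3]] * P[[5]] == 0) &
                       (P[[3]] * P[[5]] * P[[7]] == 0)
      } else {
        cond <- cond & (P[[1]] * P[[3]] * P[[7]] == 0) &
                       (P[[1]] * P[[5]] * P[[7]] == 0)
      }
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# ---- Lee-style thinning (directional simple-point deletion) --------------

# Neighbour offsets in bit order for the 8-neighbourhood configuration code.
NB_OFFSETS <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                    c(0, 1), c(1, -1), c(1, 0), c(1, 1))

# 256-entry lookup: is the centre pixel 8-simple (deletable without
# changing local topology)? Computed once by brute force: exactly one
# 8-connected foreground component in the neighbourhood AND exactly one
# 4-connected background component touching a 4-neighbour of the centre.
simple_point_lut <- local({
  lut <- NULL
  function() {
    if (!is.null(lut)) return(lut)
    count_components <- function(pos, cheby) {
      n <- nrow(pos)
      if (n == 0L) return(0L)
      seen <- rep(FALSE, n); comps <- 0L
      for (s in seq_len(n)) {
        if (seen[s]) next
        comps <- comps + 1L
        stack <- s; seen[s] <- TRUE
        while (length(stack)) {
          i <- stack[[1]]; stack <- stack[-1]
          dy <- abs(pos[, 1] - pos[i, 1]); dx <- abs(pos[, 2] - pos[i, 2])
          adj <- if (cheby) (pmax(dy, dx) == 1) else (dy + dx == 1)
          nxt <- which(adj & !seen)
          if (length(nxt)) { seen[nxt] <- TRUE; stack <- c(stack, nxt) }
        }
      }
      comps
    }
    out <- logical(256)
    four_nb <- c(2L, 4L, 5L, 7L)  # rows of NB_OFFSETS that are 4-neighbours
    for (code in 0:255) {
      bits <- bitwAnd(code, 2^(0:7)) > 0
      fg <- NB_OFFSETS[bits, , drop = FALSE]
      bg <- NB_OFFSETS[!bits, , drop = FALSE]
      if (nrow(fg) == 0L) { out[code + 1] <- FALSE; next }  # isolated point
      c_fg <- count_components(fg, cheby = TRUE)
      if (c_fg != 1L) { out[code + 1] <- FALSE; next }
      # 4-connected background components that touch a 4-neighbour slot
      if (nrow(bg) == 0L) { out[code + 1] <- FALSE; next }  # interior point
      # label bg components (4-adjacency within the ring)
      n <- nrow(bg); lab <- integer(n); cur <- 0L
      for (s in seq_len(n)) {
        if (lab[s] > 0L) next
        cur <- cur + 1L; stack <- s; lab[s] <- cur
        while (length(stack)) {
          i <- stack[[1]]; stack <- stack[-1]
          adj <- which(abs(bg[, 1] - bg[i, 1]) + abs(bg[, 2] - bg[i, 2]) == 1 & lab == 0L)
          if (length(adj)) { lab[adj] <- cur; stack <- c(stack, adj) }
        }
      }
      is4 <- bg[, 1]^2 + bg[, 2]^2 == 1
      out[code + 1] <- length(unique(lab[is4])) == 1L && any(is4)
    }
    lut <<- out
    lut
  }
})

config_code <- function(m) {
  code <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(NB_OFFSETS))) {
    code <- code + as.integer(2^(i - 1)) *
      (nb_at(m, NB_OFFSETS[i, 1], NB_OFFSETS[i, 2]) > 0)
  }
  code
}

thin_lee <- function(m) {
  m <- m * 1
  lut <- simple_point_lut()
  h <- nrow(m); w <- ncol(m)
  dirs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  code_of <- function(r, c) {
    code <- 0L
    for (i in seq_len(8)) {
      rr <- r + NB_OFFSETS[i, 1]; cc <- c + NB_OFFSETS[i, 2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && m[rr, cc] > 0)
        code <- code + as.integer(2^(i - 1))
    }
    code
  }
  repeat {
    deleted <- FALSE
    for (d in seq_len(4)) {
      nbc <- neighbour_count(m)
      border <- m > 0 & nb_at(m, dirs[d, 1], dirs[d, 2]) == 0
      cand <- border & nbc >= 2 & lut[config_code(m) + 1L]
      yx <- which_yx(cand)
      if (nrow(yx) == 0L) next
      # sequential deletion with re-check keeps the thinning topology-safe
      for (k in seq_len(nrow(yx))) {
        r <- yx[k, 1] + 1L; c <- yx[k, 2] + 1L
        code <- code_of(r, c)
        if (lut[code + 1L] && sum(bitwAnd(code, 2^(0:7)) > 0) >= 2) {
          m[r, c] <- 0
          deleted <- TRUE
        }
      }
    }
    if (!deleted) break
  }
  m == 1
}

#' Skeletonise a vessel mask
#'
#' Iterative, topology-preserving thinning of the refined mask to a
#' single-pixel-wide centreline. "zhang" is the classical Zhang-Suen
#' two-subiteration scheme; "lee" deletes simple (topology-neutral) border
#' points in four directional subcycles with sequential re-checking,
#' preserving endpoints.
#'
#' @param mask A `zv_mask` or logical matrix.
#' @param params A [skeleton_params()] object.
#' @return A `zv_skeleton` object (skeleton only; branchpoints unset).
#' @export
skeletonize <- function(mask, params = skeleton_params()) {
  m <- as_mask_matrix(mask)
  skel <- if (!any(m)) m else switch(params$method,
                                     zhang = thin_zhang(m),
                                     lee = thin_lee(m))
  structure(list(skeleton = skel, method = params$method,
                 endpoints = NULL, branchpoints_raw = NULL,
                 branchpoints_filtered = NULL),
            class = "zv_skeleton")
}

#' @export
print.zv_skeleton <- function(x, ...) {
  cat(sprintf("<zv_skeleton> [%s] %d px", x$method, sum(x$skeleton)))
  if (!is.null(x$branchpoints_raw))
    cat(sprintf(", %d raw branchpoint(s)", nrow(x$branchpoints_raw)))
  if (!is.null(x$branchpoints_filtered))
    cat(sprintf(", %d filtered", nrow(x$branchpoints_filtered)))
  cat("\n")
  invisible(x)
}

#' Detect branchpoints and endpoints
#'
#' A branchpoint is a skeleton pixel whose 3x3 neighbourhood contains at
#' least 3 other skeleton pixels (inclusive rule, the default: a degree-3
#' pixel is the canonical bifurcation); the strict rule requires >= 4.
#' Endpoints have exactly one skeleton neighbour. Points are reported in
#' raster order as 0-based (y, x).
#'
#' @param skel A `zv_skeleton`.
#' @param params A [skeleton_params()] object.
#' @return The `zv_skeleton` with `branchpoints_raw` and `endpoints` set.
#' @export
detect_branchpoints <- function(skel, params = skeleton_params()) {
  stopifnot(inherits(skel, "zv_skeleton"))
  s <- skel$skeleton
  nbc <- neighbour_count(s)
  min_nb <- if (params$branch_rule == "strict") 4 else 3
  skel$branchpoints_raw <- which_yx(s & nbc >= min_nb)
  skel$endpoints <- which_yx(s & nbc == 1)
  skel
}

#' De-cluster branchpoints by minimum distance
#'
#' Greedy raster-order retention: a raw branchpoint is kept iff its
#' Euclidean distance to every previously kept point is at least
#' `min_branch_dist_px`. The retained set is deterministic and all pairwise
#' distances meet the threshold.
#'
#' @inheritParams detect_branchpoints
#' @return The `zv_skeleton` with `branchpoints_filtered` set.
#' @export
filter_branchpoints <- function(skel, params = skeleton_params()) {
  stopifnot(inherits(skel, "zv_skeleton"))
  if (is.null(skel$branchpoints_raw))
    stop("run detect_branchpoints() first")
  skel$branchpoints_filtered <-
    greedy_min_dist(skel$branchpoints_raw, params$min_branch_dist_px)
  skel
}

# greedy raster-order minimum-distance subset selection
greedy_min_dist <- function(points, min_dist) {
  n <- nrow(points)
  if (n == 0L) return(points)
  keep <- logical(n)
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_len(n)) {
    if (length(ky) == 0L ||
        all((ky - points[i, 1])^2 + (kx - points[i, 2])^2 >= min_dist^2)) {
      keep[i] <- TRUE
      ky <- c(ky, points[i, 1]); kx <- c(kx, points[i, 2])
    }
  }
  points[keep, , drop = FALSE]
}

#' Decompose the skeleton into vessel segments
#'
#' Removes raw branchpoint pixels and labels the remaining 8-connected
#' skeleton pieces; each becomes one segment with `length_px` equal to its
#' pixel count. Segment IDs follow raster order of first pixels. The raw
#' (pre-de-clustering) branchpoints are removed so segments never span a
#' junction.
#'
#' @inheritParams filter_branchpoints
#' @return Tibble with columns `segment_id`, `length_px`, `n_pixels`,
#'   `pixel_coords` (list of (y, x) matrices).
#' @export
decompose_segments <- function(skel) {
  stopifnot(inherits(skel, "zv_skeleton"))
  if (is.null(skel$branchpoints_raw))
    stop("run detect_branchpoints() first")
  s <- skel$skeleton
  bp <- skel$branchpoints_raw
  if (nrow(bp) > 0L) s[yx_to_idx(bp, nrow(s))] <- FALSE
  lab <- label_components(s, 8)
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(segment_id = integer(0), length_px = numeric(0),
                          n_pixels = integer(0), pixel_coords = list()))
  }
  coords <- lapply(seq_len(n), function(i) which_yx(lab == i))
  tibble::tibble(
    segment_id = seq_len(n),
    length_px = vapply(coords, nrow, integer(1)) * 1.0,
    n_pixels = vapply(coords, nrow, integer(1)),
    pixel_coords = coords
  )
}

#' Estimate per-pixel vessel diameters
#'
#' Diameter at a skeleton pixel is twice the Euclidean distance transform
#' of the vessel mask at that pixel (maximum inscribed circle diameter).
#'
#' @param mask The vessel mask the skeleton was derived from.
#' @param segments Segment tibble from [decompose_segments()].
#' @return The segment tibble with `diameters_px` (list) and
#'   `mean_diameter_px` columns added.
#' @export
estimate_diameters <- function(mask, segments) {
  m <- as_mask_matrix(mask)
  if (nrow(segments) == 0L) {
    segments$diameters_px <- list()
    segments$mean_diameter_px <- numeric(0)
    return(segments)
  }
  dm <- edt(m)
  h <- nrow(m)
  segments$diameters_px <- lapply(segments$pixel_coords, function(yx) {
    idx <- yx_to_idx(yx, h)
    if (any(!m[idx]))
      stop("skeleton pixel outside mask: skeleton/mask mismatch")
    2 * dm[idx]
  })
  segments$mean_diameter_px <-
    vapply(segments$diameters_px, mean, numeric(1))
  segments
}

#' Pixel-space network metrics
#'
#' Network length is the total skeleton pixel count (the package also
#' reports `network_length_diag_px`, an approximate geodesic length that
#' weights diagonal links by sqrt(2); this is a convenience column, not
#' the default convention). Vessel density is the mean, over square tiles
#' of `density_tile_um2` physical area (partial edge tiles dropped), of
#' the within-tile vessel pixel fraction. Branchpoint count uses the
#' de-clustered (filtered) set.
#'
#' @param skel A `zv_skeleton` with filtered branchpoints.
#' @param segments Segment tibble with diameters.
#' @param mask The vessel mask.
#' @param scale_px_per_um Pixels per micrometre.
#' @param params A [skeleton_params()] object.
#' @return One-row tibble of pixel-space metrics.
#' @export
network_metrics <- function(skel, segments, mask, scale_px_per_um,
                            params = skeleton_params()) {
  stopifnot(inherits(skel, "zv_skeleton"))
  if (is.null(skel$branchpoints_filtered))
    stop("run filter_branchpoints() first")
  m <- as_mask_matrix(mask)
  s <- skel$skeleton
  n_px <- sum(s)
  # diagonal links: count each diagonally adjacent skeleton pair once
  n_diag <- sum(s & nb_at(s, -1, -1) > 0) + sum(s & nb_at(s, -1, 1) > 0)
  tile_side <- round(sqrt(params$density_tile_um2) * scale_px_per_um)
  if (tile_side < 1) stop("density tile smaller than one pixel; check calibration")
  vessel_density <- if (!any(m)) 0 else tiled_density(m, tile_side)
  mean_diam <- if (nrow(segments) == 0L) 0 else {
    if (params$mean_diameter_over == "pixels")
      mean(unlist(segments$diameters_px))
    else mean(segments$mean_diameter_px)
  }
  tibble::tibble(
    network_length_px = n_px * 1.0,
    network_length_diag_px = n_px + (sqrt(2) - 1) * n_diag,
    vessel_density = vessel_density,
    branchpoint_count = nrow(skel$branchpoints_filtered),
    branchpoint_count_raw = nrow(skel$branchpoints_raw),
    mean_diameter_px = mean_diam,
    n_segments = nrow(segments),
    image_height_px = nrow(m),
    image_width_px = ncol(m)
  )
}

# mean over full tiles of the within-tile foreground fraction
tiled_density <- function(m, tile_side) {
  h <- nrow(m); w <- ncol(m)
  nty <- h %/% tile_side; ntx <- w %/% tile_side
  if (nty < 1 || ntx < 1) stop("image smaller than one density tile")
  sub <- m[seq_len(nty * tile_side), seq_len(ntx * tile_side), drop = FALSE] * 1
  # block-sum via dimension folding
  a <- array(sub, c(tile_side, nty, tile_side * ntx))
  rowsums <- apply(a, c(2, 3), sum)                   # nty x (tile_side*ntx)
  b <- array(rowsums, c(nty, tile_side, ntx))
  tile_sums <- apply(b, c(1, 3), sum)                 # nty x ntx
  mean(tile_sums / tile_side^2)
}
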