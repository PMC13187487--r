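# Binary image primitives: connected-component labelling with the standard
# dual convention (8-connected foreground, 4-connected background), size
# filtering, and bounded hole filling.

#' Label connected components of a binary mask
#'
#' Foreground components are labelled with consecutive positive integers in
#' raster order of each component's first pixel (top-to-bottom, left-to-right),
#' so labelling is fully deterministic.
#'
#' @param mask Logical matrix (or `zv_mask`).
#' @param connectivity 8 (default, foreground convention) or 4.
#' @return Integer matrix of labels; 0 is background.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- as_mask_matrix(mask)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(m * 1)  # 4-connected
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nl <- max(lab)
  if (nl == 0L) return(lab)
  if (connectivity == 8 && nl > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    # merge labels that touch only diagonally
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # \ diagonal
    a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # / diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nl)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nl), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_raster(lab)
}

# Renumber positive labels 1..m by raster order of first occurrence.
relabel_raster <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(lab)
  h <- nrow(lab)
  y <- (idx - 1L) %% h
  x <- (idx - 1L) %/% h
  raster_key <- y * ncol(lab) + x
  labs <- lab[idx]
  first_key <- tapply(raster_key, labs, min)
  new_id <- integer(max(lab))
  new_id[as.integer(names(first_key))] <- rank(first_key, ties.method = "first")
  lab[idx] <- new_id[labs]
  lab
}

component_sizes <- function(lab) {
  nl <- max(lab)
  if (nl == 0L) return(integer(0))
  tabulate(lab[lab > 0L], nbins = nl)
}

#' Remove small foreground objects
#'
#' Deletes 8-connected foreground components with area strictly below
#' `min_px` (area >= `min_px` survives).
#'
#' @param mask Logical matrix.
#' @param min_px Minimum surviving component area in pixels.
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_px) {
  m <- as_mask_matrix(mask)
  if (min_px <= 1) return(m)
  lab <- label_components(m, 8)
  sz <- component_sizes(lab)
  if (length(sz) == 0L) return(m)
  drop <- which(sz < min_px)
  if (length(drop)) m[lab %in% drop] <- FALSE
  m
}

#' Fill small holes in a binary mask
#'
#' A hole is a 4-connected background component not touching the image
#' border; holes with area strictly below `max_px` are filled.
#'
#' @param mask Logical matrix.
#' @param max_px Holes with area < `max_px` are filled.
#' @return Logical matrix.
#' @export
fill_small_holes <- function(mask, max_px) {
  m <- as_mask_matrix(mask)
  if (max_px <= 1) return(m)
  bg <- !m
  lab <- label_components(bg, 4)
  if (max(lab) == 0L) return(m)
  h <- nrow(lab); w <- ncol(lab)
  border <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border <- border[border > 0L]
  sz <- component_sizes(lab)
  fill <- setdiff(which(sz < max_px), border)
  if (length(fill)) m[lab %in% fill] <- TRUE
  m
}

# Exact Euclidean distance transform: per foreground pixel, distance to the
# nearest background pixel (0 on background).
edt <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(!m)) stop("distance transform undefined: mask has no background")
  d <- EBImage::distmap(m * 1, metric = "euclidean")
  matrix(as.numeric(d), nrow(m), ncol(m))
}

# Distance from every pixel to the nearest TRUE pixel of `target`
# (0 on target pixels); Inf everywhere if target is empty.
dist_to_set <- function(target) {
  t <- as_mask_matrix(target)
  if (!any(t)) return(matrix(Inf, nrow(t), ncol(t)))
  d <- EBImage::distmap((!t) * 1, metric = "euclidean")
  matrix(as.numeric(d), nrow(t), ncol(t))
}

# Count of TRUE 8-neighbours at every pixel (centre excluded).
neighbour_count <- function(mask) {
  m <- as_mask_matrix(mask) * 1
  s <- matrix(0, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    s <- s + shift_mat(m, dy, dx, 0)
  }
  s
}
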