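# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# Otsu: exhaustive sweep over all 255 candidate thresholds, computing the
# between-class variance from first principles.
oracle_otsu <- function(vals) {
  vals <- as.integer(vals)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(vals); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Jaccard from raw set arithmetic on pixel index sets.
oracle_jaccard <- function(a, b) {
  ia <- which(a); ib <- which(b)
  u <- union(ia, ib)
  if (length(u) == 0L) return(1)
  length(intersect(ia, ib)) / length(u)
}

# Connected-component count by scanline flood fill (queue-based BFS).
oracle_component_count <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start; seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
        }
      }
    }
  }
  count
}

# Per-pixel diameter by exhaustive nearest-background search.
oracle_diameter <- function(mask, yx) {
  bg <- which(!mask)
  h <- nrow(mask)
  by <- (bg - 1L) %% h; bx <- (bg - 1L) %/% h
  apply(yx, 1, function(p) 2 * sqrt(min((by - p[1])^2 + (bx - p[2])^2)))
}

# Elementwise max projection by explicit looping over z.
oracle_max_project <- function(vox_zyx) {
  d <- dim(vox_zyx)
  out <- matrix(-Inf, d[2], d[3])
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3]))
    out[y, x] <- max(out[y, x], vox_zyx[z, y, x])
  out
}

# small deterministic random binary mask
random_mask <- function(h, w, p = 0.3) matrix(stats::runif(h * w) < p, h, w)

# projection wrapper for raw matrices in tests
proj_of <- function(m, bit_depth = 16, z_depth_um = 100) {
  zebravasc::projection_image(m, bit_depth = bit_depth,
                              pixel_size_um = 1 / 1.2,
                              z_depth_um = z_depth_um)
}
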