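plus_skeleton <- function(arm = 10, h = 2 * arm + 5) {
  c0 <- arm + 3
  m <- matrix(FALSE, h, h)
  m[c0, (c0 - arm):(c0 + arm)] <- TRUE
  m[(c0 - arm):(c0 + arm), c0] <- TRUE
  m
}

test_that("thinning leaves 1-px lines unchanged and reduces blocks", {
  line <- matrix(FALSE, 9, 20); line[5, 3:18] <- TRUE
  for (meth in c("lee", "zhang")) {
    sk <- skeletonize(line, skeleton_params(method = meth))
    expect_identical(sk$skeleton, line, label = meth)
  }
  sq <- matrix(FALSE, 11, 11); sq[3:9, 3:9] <- TRUE
  for (meth in c("lee", "zhang")) {
    sk <- skeletonize(sq, skeleton_params(method = meth))
    expect_lte(sum(sk$skeleton), 13)
    expect_equal(oracle_component_count(sk$skeleton, 8), 1)
    expect_true(all(sk$skeleton <= sq))
  }
  empty <- skeletonize(matrix(FALSE, 5, 5))
  expect_false(any(empty$skeleton))
})

test_that("a thick bar thins to a single path spanning its long axis", {
  bar <- matrix(FALSE, 15, 60); bar[6:10, 4:53] <- TRUE
  for (meth in c("lee", "zhang")) {
    sk <- skeletonize(bar, skeleton_params(method = meth))
    s <- sk$skeleton
    expect_equal(oracle_component_count(s, 8), 1)
    det <- detect_branchpoints(sk)
    expect_equal(nrow(det$endpoints), 2, label = meth)
    xs <- range(which(colSums(s) > 0)) - 1
    expect_lte(abs(xs[1] - 3), 3)
    expect_lte(abs(xs[2] - 52), 3)
  }
})

test_that("Zhang skeletons contain no 2x2 blocks; Lee stays near-thin", {
  g <- generate_phantom(phantom_spec(seed = 2))
  seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
  zs <- skeletonize(seg$mask, skeleton_params(method = "zhang"))$skeleton
  two_by_two <- zs[-nrow(zs), -ncol(zs)] & zs[-1, -ncol(zs)] &
    zs[-nrow(zs), -1] & zs[-1, -1]
  expect_false(any(two_by_two))
  ls <- skeletonize(seg$mask, skeleton_params(method = "lee"))$skeleton
  lblock <- ls[-nrow(ls), -ncol(ls)] & ls[-1, -ncol(ls)] &
    ls[-nrow(ls), -1] & ls[-1, -1]
  expect_lte(sum(lblock) / max(sum(ls), 1), 0.005)
})

test_that("branchpoint and endpoint detection follows the 3x3 neighbour rule", {
  # ideal plus: centre has 4 neighbours and each arm-first pixel has 4
  # (centre, next arm pixel, two diagonal arm-firsts), so the neighbour
  # rule flags a 5-pixel junction cluster; de-clustering reduces it to one
  pl <- plus_skeleton(10)
  sk <- detect_branchpoints(skeletonize(pl))
  raw <- sk$branchpoints_raw
  expect_equal(nrow(raw), 5)
  expect_true(all(paste(raw[, 1], raw[, 2]) %in%
                  paste(c(11, 12, 12, 12, 13), c(12, 11, 12, 13, 12))))
  expect_equal(nrow(sk$endpoints), 4)
  filt <- filter_branchpoints(sk, skeleton_params())
  expect_equal(nrow(filt$branchpoints_filtered), 1)
  line <- matrix(FALSE, 7, 30); line[4, 3:28] <- TRUE
  skl <- detect_branchpoints(skeletonize(line))
  expect_equal(nrow(skl$branchpoints_raw), 0)
  expect_equal(nrow(skl$endpoints), 2)
})

test_that("the T-junction centre is flagged inclusively but not strictly", {
  # constructed directly: re-thinning would remove the redundant centre
  tj <- matrix(FALSE, 15, 15)
  tj[8, 3:13] <- TRUE; tj[3:8, 8] <- TRUE
  sk <- structure(list(skeleton = tj, method = "lee", endpoints = NULL,
                       branchpoints_raw = NULL, branchpoints_filtered = NULL),
                  class = "zv_skeleton")
  incl <- detect_branchpoints(sk, skeleton_params(branch_rule = "inclusive"))
  centre <- paste(7, 7)  # 0-based (y, x) of the degree-3 junction pixel
  expect_true(centre %in% paste(incl$branchpoints_raw[, 1],
                                incl$branchpoints_raw[, 2]))
  strict <- detect_branchpoints(sk, skeleton_params(branch_rule = "strict"))
  expect_false(centre %in% paste(strict$branchpoints_raw[, 1],
                                 strict$branchpoints_raw[, 2]))
})

test_that("branchpoint de-clustering follows greedy raster-order retention", {
  sk <- structure(list(skeleton = matrix(FALSE, 50, 50), method = "lee",
                       branchpoints_raw = cbind(y = c(10, 10), x = c(10, 20)),
                       endpoints = NULL, branchpoints_filtered = NULL),
                  class = "zv_skeleton")
  near <- filter_branchpoints(sk, skeleton_params(min_branch_dist_px = 30))
  expect_equal(nrow(near$branchpoints_filtered), 1)
  expect_equal(near$branchpoints_filtered[1, ], c(y = 10, x = 10))
  sk$branchpoints_raw <- cbind(y = c(10, 10), x = c(5, 45))
  far <- filter_branchpoints(sk, skeleton_params(min_branch_dist_px = 30))
  expect_equal(nrow(far$branchpoints_filtered), 2)
  sk$branchpoints_raw <- cbind(y = numeric(0), x = numeric(0))
  none <- filter_branchpoints(sk, skeleton_params())
  expect_equal(nrow(none$branchpoints_filtered), 0)
})

test_that("de-clustering is deterministic with all pairwise distances enforced", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    pts <- cbind(y = sample(0:199, n, TRUE), x = sample(0:199, n, TRUE))
    pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
    sk <- structure(list(skeleton = matrix(FALSE, 2, 2), method = "lee",
                         branchpoints_raw = pts, endpoints = NULL,
                         branchpoints_filtered = NULL), class = "zv_skeleton")
    f1 <- filter_branchpoints(sk, skeleton_params())$branchpoints_filtered
    f2 <- filter_branchpoints(sk, skeleton_params())$branchpoints_filtered
    expect_identical(f1, f2)
    expect_true(all(paste(f1[, 1], f1[, 2]) %in% paste(pts[, 1], pts[, 2])))
    if (nrow(f1) > 1) {
      d <- as.matrix(dist(f1)); diag(d) <- Inf
      expect_gte(min(d), 30)
    }
  }
})

test_that("segment decomposition conserves skeleton pixels", {
  # plus: the 5-pixel junction cluster is removed, leaving 4 arms of 9
  pl <- plus_skeleton(10)
  sk <- detect_branchpoints(skeletonize(pl))
  segs <- decompose_segments(sk)
  expect_equal(nrow(segs), 4)
  expect_true(all(segs$length_px == 9))
  expect_equal(sum(segs$length_px) + nrow(sk$branchpoints_raw), sum(pl))
  line <- matrix(FALSE, 5, 30); line[3, 3:27] <- TRUE
  skl <- detect_branchpoints(skeletonize(line))
  sl <- decompose_segments(skl)
  expect_equal(nrow(sl), 1)
  expect_equal(sl$length_px, 25)
  expect_equal(nrow(decompose_segments(
    detect_branchpoints(skeletonize(matrix(FALSE, 5, 5))))), 0)
  # conservation on a realistic skeleton
  g <- generate_phantom(phantom_spec(seed = 3))
  seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
  skg <- detect_branchpoints(skeletonize(seg$mask))
  sg <- decompose_segments(skg)
  expect_equal(sum(sg$length_px) + nrow(skg$branchpoints_raw),
               sum(skg$skeleton))
})

test_that("inscribed-circle diameters follow the distance transform", {
  band <- matrix(FALSE, 11, 40); band[4:8, ] <- TRUE
  segs <- tibble::tibble(segment_id = 1L, length_px = 30, n_pixels = 30L,
                         pixel_coords = list(cbind(y = rep(5, 30), x = 5:34)))
  d <- estimate_diameters(band, segs)
  expect_true(all(abs(d$diameters_px[[1]] - 5) <= 1))
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  s1 <- tibble::tibble(segment_id = 1L, length_px = 1, n_pixels = 1L,
                       pixel_coords = list(cbind(y = 2, x = 2)))
  expect_equal(estimate_diameters(one, s1)$diameters_px[[1]], 2)
  # disc of radius 10: centre diameter within 1 px of 20
  disc <- matrix(FALSE, 25, 25)
  for (y in 0:24) for (x in 0:24) if ((y - 12)^2 + (x - 12)^2 <= 100)
    disc[y + 1, x + 1] <- TRUE
  sd_ <- tibble::tibble(segment_id = 1L, length_px = 1, n_pixels = 1L,
                        pixel_coords = list(cbind(y = 12, x = 12)))
  expect_lte(abs(estimate_diameters(disc, sd_)$diameters_px[[1]] - 20), 1)
  # skeleton pixel outside the mask is an invalid state
  bad <- tibble::tibble(segment_id = 1L, length_px = 1, n_pixels = 1L,
                        pixel_coords = list(cbind(y = 0, x = 0)))
  expect_error(estimate_diameters(band, bad), "mismatch")
})

test_that("network metrics handle saturated and empty inputs", {
  full <- matrix(TRUE, 48, 48)
  sk <- detect_branchpoints(skeletonize(matrix(FALSE, 48, 48)))
  sk <- filter_branchpoints(sk, skeleton_params())
  segs <- decompose_segments(sk)
  segs$diameters_px <- list(); segs$mean_diameter_px <- numeric(0)
  rec <- network_metrics(sk, segs, full, scale_px_per_um = 1.2)
  expect_equal(rec$vessel_density, 1)
  expect_equal(rec$network_length_px, 0)
  expect_equal(rec$branchpoint_count, 0)
})

test_that("network length and junction counts recover phantom ground truth", {
  # ladder with ~600 true centreline px and 10 junctions >= 40 px apart
  g <- generate_phantom(phantom_spec(shape = c(140, 260), n_branches = 5,
                                     seed = 4))
  expect_equal(nrow(g$junctions), 10)
  seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
  res <- compute_image_metrics(seg$mask, 1.2, 100)
  expect_equal(res$record$branchpoint_count, 10)
  expect_lt(abs(res$record$network_length_px - g$total_centreline_px) /
              g$total_centreline_px, 0.1)
})

test_that("metrics are translation invariant up to density tile phase", {
  g <- generate_phantom(phantom_spec(shape = c(140, 260), n_branches = 4,
                                     noise_model = "none"))
  m <- g$true_mask
  shifted <- shift_base <- matrix(FALSE, 160, 280)
  shift_base[1:140, 1:260] <- m
  shifted[8:147, 6:265] <- m
  r1 <- compute_image_metrics(new_mask(shift_base, "a"), 1.2, 100)$record
  r2 <- compute_image_metrics(new_mask(shifted, "b"), 1.2, 100)$record
  expect_equal(r1$network_length_px, r2$network_length_px)
  expect_equal(r1$branchpoint_count, r2$branchpoint_count)
  expect_equal(r1$mean_diameter_px, r2$mean_diameter_px, tolerance = 1e-8)
  expect_lt(abs(r1$vessel_density - r2$vessel_density) /
              max(r1$vessel_density, 1e-9), 0.02)
})
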