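test_that("box and half-plane regions rasterise to exact pixel counts", {
  box <- roi_spec("b", "box", corners = c(0, 0, 9, 9))
  expect_equal(sum(rasterize_roi(box, c(20, 20))), 100)
  hp <- roi_spec("h", "half_plane", axis = "x", value = 10, side = "less")
  expect_equal(sum(rasterize_roi(hp, c(20, 20))), 200)
  hp2 <- roi_spec("h2", "half_plane", axis = "y", value = 5, side = "geq")
  expect_equal(sum(rasterize_roi(hp2, c(20, 20))), 15 * 20)
})

test_that("polygon rasterisation follows even-odd with boundary included", {
  tri <- roi_spec("t", "polygon", vertices = rbind(c(0, 0), c(0, 9), c(9, 0)))
  m <- rasterize_roi(tri, c(12, 12))
  # oracle: per-pixel half-plane test of the triangle y>=0, x>=0, y+x<=9
  oracle <- outer(0:11, 0:11, function(y, x) y + x <= 9)
  expect_identical(m, oracle)
  expect_equal(sum(m), 55)
  # continuous area crosscheck (Pick): interior + boundary/2 - 1 = 40.5
  interior <- sum(outer(0:11, 0:11, function(y, x) y > 0 & x > 0 & y + x < 9))
  boundary <- sum(m) - interior
  expect_equal(interior + boundary / 2 - 1, 40.5)
  expect_error(roi_spec("d", "polygon",
                        vertices = rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
})

test_that("polygon containment agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(31)
  for (i in 1:5) {
    n <- sample(3:7, 1)
    v <- cbind(runif(n, 0, 19), runif(n, 0, 19))
    spec <- tryCatch(roi_spec("p", "polygon", vertices = v),
                     error = function(e) NULL)
    if (is.null(spec)) next
    m <- rasterize_roi(spec, c(20, 20))
    pts <- cbind(rep(0:19, 20), rep(0:19, each = 20))
    inside <- mgcv::in.out(rbind(v, v[1, ]), pts)
    # the oracle excludes boundary points; ours includes them
    disagree <- which(matrix(inside, 20, 20, byrow = FALSE) != m)
    if (length(disagree)) {
      # every disagreement must lie on a polygon edge (boundary handling)
      yx <- cbind((disagree - 1) %% 20, (disagree - 1) %/% 20)
      on_b <- zebravasc:::point_in_polygon(yx[, 1], yx[, 2], v)
      expect_true(all(m[disagree] >= inside[disagree]))
    } else succeed()
  }
})

test_that("the full-image ROI reproduces whole-image metrics field-for-field", {
  g <- generate_phantom(phantom_spec(shape = c(140, 260), n_branches = 4))
  seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
  whole <- analyze_roi(seg$mask, NULL, 1.2, 100)
  full <- analyze_roi(seg$mask,
                      roi_spec("all", "box", corners = c(0, 0, 139, 259)),
                      1.2, 100)
  for (nm in setdiff(names(whole$record), "roi_id"))
    expect_identical(whole$record[[nm]], full$record[[nm]], label = nm)
})

test_that("network length is monotone under ROI nesting", {
  g <- generate_phantom(phantom_spec(shape = c(140, 260), n_branches = 4))
  seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
  inner <- analyze_roi(seg$mask, roi_spec("i", "box", corners = c(20, 20, 100, 180)),
                       1.2, 100)
  outer_ <- analyze_roi(seg$mask, roi_spec("o", "box", corners = c(0, 0, 139, 259)),
                        1.2, 100)
  expect_lte(inner$record$network_length_px, outer_$record$network_length_px)
})

test_that("two half-plane ROIs tiling the image conserve network length", {
  g <- generate_phantom(phantom_spec(noise_model = "none"))
  m <- new_mask(g$true_mask, "truth")
  whole <- analyze_roi(m, NULL, 1.2, 100)$record$network_length_px
  left <- analyze_roi(m, roi_spec("L", "half_plane", axis = "x", value = 240),
                      1.2, 100)$record$network_length_px
  right <- analyze_roi(m, roi_spec("R", "half_plane", axis = "x", value = 240,
                                   side = "geq"), 1.2, 100)$record$network_length_px
  # cutting the mask can only lose a bounded number of pixels at the seam
  crossings <- sum(g$true_mask[, 240] & g$true_mask[, 241])
  expect_gte(left + right, whole - crossings)
  expect_lte(left + right, whole + crossings + 10)
})

test_that("mirror-symmetric vasculature yields identical left/right metrics", {
  g <- generate_phantom(phantom_spec(shape = c(260, 480)))
  seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
  half <- seg$mask$pixels[, 1:240]
  sym <- new_mask(cbind(half, half[, 240:1]), "sym")
  left <- analyze_roi(sym, roi_spec("L", "half_plane", axis = "x", value = 240),
                      1.2, 100)$record
  right <- analyze_roi(sym, roi_spec("R", "half_plane", axis = "x", value = 240,
                                     side = "geq"), 1.2, 100)$record
  for (nm in c("network_length_px", "branchpoint_count", "vessel_density",
               "mean_diameter_px", "normalised_network_length"))
    expect_identical(left[[nm]], right[[nm]], label = nm)
})

test_that("empty intersections warn and out-of-image ROIs error", {
  m <- new_mask(matrix(FALSE, 50, 50) | rbind(matrix(FALSE, 25, 50),
                                              matrix(TRUE, 25, 50)), "m")
  expect_warning(res <- analyze_roi(m, roi_spec("e", "box", corners = c(0, 0, 20, 20)),
                                    1.2, 100), "no vessel")
  expect_equal(res$record$network_length_px, 0)
})
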