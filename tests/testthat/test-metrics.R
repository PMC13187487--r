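test_that("MAD filter reproduces the worked example and degenerate cases", {
  r <- mad_filter(c(1, 2, 3, 4, 100))
  expect_equal(r$bounds, c(2, 6))
  expect_equal(r$retained, c(2, 3, 4))
  const <- mad_filter(c(5, 5, 5))
  expect_equal(const$retained, c(5, 5, 5))
  expect_equal(const$bounds, c(5, 5))
  expect_error(mad_filter(numeric(0)), "at least one")
  expect_error(mad_params(lower_mult = 0), "> 0")
})

test_that("MAD filter retains the normal-theory fraction on Gaussian data", {
  set.seed(42)
  x <- rnorm(1000)
  frac <- length(mad_filter(x)$retained) / 1000
  theory <- pnorm(3 * 0.6745) - pnorm(-0.6745)  # ~0.7285
  expect_lt(abs(frac - theory), 0.03)
})

test_that("MAD filter is scale-equivariant with bounds bracketing the median", {
  set.seed(43)
  for (i in 1:10) {
    x <- rlnorm(sample(5:60, 1))
    a <- 2^sample(-3:3, 1)  # exact in floating point, no bound knife-edges
    fx <- mad_filter(x); fax <- mad_filter(a * x)
    expect_equal(fax$retained, a * fx$retained, tolerance = 1e-12)
    expect_true(all(fx$retained %in% x))
    m <- median(x)
    expect_lte(fx$bounds[1], m); expect_gte(fx$bounds[2], m)
  }
})

test_that("consistency-factor option widens the raw-MAD bounds", {
  x <- c(1, 2, 3, 4, 100)
  raw <- mad_filter(x, mad_params())
  cons <- mad_filter(x, mad_params(consistency = TRUE))
  expect_gt(diff(cons$bounds), diff(raw$bounds))
})

base_record <- function(len_px = 120, h = 120L, w = 120L) {
  tibble::tibble(network_length_px = len_px, network_length_diag_px = len_px,
                 vessel_density = 0.1, branchpoint_count = 4L,
                 branchpoint_count_raw = 6L, mean_diameter_px = 6,
                 n_segments = 3L, image_height_px = h, image_width_px = w)
}

test_that("pixel-to-micron conversion follows the 1.2 px/um calibration", {
  rec <- to_physical_units(base_record(120), 1.2, 100)
  expect_equal(rec$network_length_um, 100)
  expect_equal(rec$normalised_network_length, 1)
  expect_equal(rec$mean_diameter_um, 6 / 1.2)
  expect_equal(rec$branchpoint_density_per_um2, 4 / (120 * 120 / 1.2^2))
  zero <- to_physical_units(base_record(0), 1.2, 100)
  expect_equal(zero$network_length_um, 0)
  expect_equal(zero$normalised_network_length, 0)
})

test_that("doubling z-depth halves the normalised length exactly", {
  r1 <- to_physical_units(base_record(240), 1.2, 100)
  r2 <- to_physical_units(base_record(240), 1.2, 200)
  expect_identical(r1$normalised_network_length,
                   2 * r2$normalised_network_length)
})

test_that("unit conversion round-trips to 1e-9 relative tolerance", {
  set.seed(44)
  for (i in 1:10) {
    len <- runif(1, 1, 5000); scale <- runif(1, 0.3, 4)
    rec <- to_physical_units(base_record(len), scale, 77)
    expect_lt(abs(rec$network_length_um * scale - len) / len, 1e-9)
  }
  expect_error(to_physical_units(base_record(), -1, 100), "> 0")
  expect_error(to_physical_units(base_record(), 1.2, 0), "> 0")
  expect_error(to_physical_units(base_record(), 1.2, 100,
                                 normalise_by = "slices"), "n_slices")
  sl <- to_physical_units(base_record(120), 1.2, 100, n_slices = 20,
                          normalise_by = "slices")
  expect_equal(sl$normalised_network_length, 100 / 20)
})

test_that("export writes a stable summary plus flagged per-segment sheets", {
  g <- generate_phantom(phantom_spec(shape = c(140, 260), n_branches = 4))
  seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
  res <- compute_image_metrics(seg$mask, 1.2, 100, image_id = "phantomA")
  recs <- dplyr::bind_rows(res$record, res$record)
  recs$image_id[2] <- "phantomB"
  segtab <- res$segments
  d1 <- tempfile(); d2 <- tempfile()
  export_results(recs, segtab, d1, provenance = list(seed = 1))
  export_results(recs, segtab, d2, provenance = list(seed = 1))
  s1 <- read.csv(file.path(d1, "summary.csv"))
  expect_equal(nrow(s1), 2)
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  seg_csv <- read.csv(file.path(d1, "segments_phantomA.csv"))
  expect_equal(nrow(seg_csv), res$record$n_segments_pre_mad)
  expect_equal(sum(seg_csv$mad_excluded == "TRUE" | seg_csv$mad_excluded == TRUE),
               res$record$n_segments_pre_mad - res$record$n_segments_post_mad)
  expect_true(file.exists(file.path(d1, "provenance.json")))
  expect_error(export_results(recs[0, ], NULL, tempfile()), "no records")
})

test_that("post-MAD segment counts never exceed pre-MAD counts", {
  for (seed in 1:3) {
    g <- generate_phantom(phantom_spec(seed = seed, shape = c(140, 260),
                                       n_branches = 4))
    seg <- segment_projection(phantom_projection(g, z_depth_um = 100))
    rec <- compute_image_metrics(seg$mask, 1.2, 100)$record
    expect_lte(rec$n_segments_post_mad, rec$n_segments_pre_mad)
    expect_equal(rec$network_length_um,
                 rec$network_length_px / rec$scale_px_per_um)
    expect_equal(rec$normalised_network_length,
                 rec$network_length_um / rec$z_depth_um)
  }
})
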