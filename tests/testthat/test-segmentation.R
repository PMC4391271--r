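# Segmentation module: lumen detection, wall completeness, stain fraction.

test_that("blank and constant rasters yield no lumens", {
  set.seed(1)
  noise <- matrix(0.45 + rnorm(200 * 200, 0, 0.01), 200, 200)
  expect_length(detect_lumens(noise, 0.25), 0L)
  expect_identical(detect_lumens(matrix(0.5, 50, 50), 0.25), list())
  expect_error(detect_lumens(noise, -1), "pixel_size")
})

test_that("disjoint rendered vessels are recovered with accurate centroids and areas", {
  cfg <- generator_config("apical", seed = 1, pixel_size = 0.25,
                          image_shape = c(480L, 480L), n_bundles = 1,
                          ring_radius = 0, px_count_mean = 0,
                          mx_count_mean = 0, fiber_density = 0, noise_sd = 0)
  tr <- vessel_truth(x_um = c(30, 70, 90, 40, 75),
                     y_um = c(30, 25, 70, 80, 95),
                     diameter_um = c(8, 12, 16, 10, 6),
                     stain_fraction = 0.8)
  pair <- render_pair(tr, cfg)
  regs <- detect_lumens(pair$bf, cfg$pixel_size)
  expect_length(regs, 5L)
  rec <- measure_vessels(pair)
  idx <- match_vessels(rec, tr)
  expect_true(all(!is.na(idx)))
  d <- sqrt((rec$centroid_x_um - tr$x_um[idx])^2 +
              (rec$centroid_y_um - tr$y_um[idx])^2)
  expect_true(all(d <= cfg$pixel_size))                 # within 1 px
  true_area <- pi * (tr$diameter_um[idx] / 2)^2
  expect_true(all(abs(rec$area_um2 - true_area) / true_area < 0.05))
  # equivalent-diameter invariant: D = 2 sqrt(A / pi), and close to truth
  expect_equal(rec$diameter_um, 2 * sqrt(rec$area_um2 / pi),
               tolerance = 1e-9)
  expect_true(all(abs(rec$diameter_um - tr$diameter_um[idx]) <=
                    2 * cfg$pixel_size))
})

test_that("touching lumens are split by the watershed", {
  img <- matrix(0.1, 160, 160)
  xy <- expand.grid(r = 1:160, c = 1:160)
  d1 <- sqrt((xy$r - 80)^2 + (xy$c - 62)^2)
  d2 <- sqrt((xy$r - 80)^2 + (xy$c - 98)^2)
  img[d1 <= 20 | d2 <= 20] <- 0.9          # two discs overlapping slightly
  regs <- detect_lumens(img, 0.25, params = list(max_area = 1e4,
                                                 refine = FALSE))
  expect_length(regs, 2L)
})

test_that("wall completeness reads the drawn arc extent", {
  full <- single_vessel_fixture(d = 16, wall_state = "full",
                                stain_fraction = 0.8)
  rec <- measure_vessels(full$pair)
  expect_equal(rec$wall_completeness, 1.0)

  partial <- single_vessel_fixture(d = 16, wall_state = "partial",
                                   wall_completeness = 0.75,
                                   stain_fraction = 0.3)
  rec <- measure_vessels(partial$pair)
  expect_lt(abs(rec$wall_completeness - 0.75), 0.02)

  absent <- single_vessel_fixture(d = 16, wall_state = "absent",
                                  stain_fraction = 0)
  rec <- measure_vessels(absent$pair)
  expect_lte(rec$wall_completeness, 0.05)
})

test_that("exposure normalization keeps stained arcs and rejects the autofluorescence floor", {
  expect_false(any(apply_exposure_normalization(matrix(0.3, 64, 64))))
  set.seed(7)
  sigma <- 0.01
  ef <- matrix(0.05 + rnorm(300 * 300, 0, sigma), 300, 300)
  floor_px <- cbind(sample(140, 2000, TRUE), sample(140, 2000, TRUE))
  ef[floor_px] <- ef[floor_px] + 2 * sigma        # autofluorescence
  arc_px <- cbind(151:200, 151:200)               # disjoint from the floor
  ef[arc_px] <- 0.05 + 20 * sigma                 # stained arcs
  mask <- apply_exposure_normalization(ef, k_ef = 6)
  expect_true(all(mask[arc_px]))
  expect_false(any(mask[floor_px]))
  expect_false(any(apply_exposure_normalization(ef, k_ef = Inf)))
})

test_that("stain fraction reads the drawn arc extent", {
  ring <- single_vessel_fixture(d = 16, stain_fraction = 1.0)
  rec <- measure_vessels(ring$pair)
  expect_equal(rec$stain_fraction, 1.0)

  arc <- single_vessel_fixture(d = 16, stain_fraction = 0.75)
  rec <- measure_vessels(arc$pair)
  expect_lt(abs(rec$stain_fraction - 0.75), 0.02)

  blank <- single_vessel_fixture(d = 16, wall_state = "full",
                                 stain_fraction = 0)
  blank$pair$ef <- matrix(0.05, nrow(blank$pair$ef), ncol(blank$pair$ef))
  rec <- measure_vessels(blank$pair)
  expect_equal(rec$stain_fraction, 0)
})

test_that("stain fraction grows monotonically with the rendered arc", {
  fr <- seq(0.1, 0.9, by = 0.2)
  meas <- vapply(fr, function(f) {
    fx <- single_vessel_fixture(d = 16, stain_fraction = f)
    measure_vessels(fx$pair)$stain_fraction
  }, numeric(1))
  expect_true(all(diff(meas) > -0.005))
  expect_true(all(abs(meas - fr) < 0.03))
})

test_that("measurements are invariant to positive intensity rescaling and deterministic", {
  fx <- single_vessel_fixture(d = 12, stain_fraction = 0.7, noise_sd = 0.01)
  r1 <- measure_vessels(fx$pair)
  scaled <- image_pair(fx$pair$bf * 2.5, fx$pair$ef * 2.5,
                       fx$pair$pixel_size)
  r2 <- measure_vessels(scaled)
  expect_equal(r1$area_um2, r2$area_um2, tolerance = 1e-6)
  expect_equal(r1$wall_completeness, r2$wall_completeness)
  expect_equal(r1$stain_fraction, r2$stain_fraction)
  expect_identical(r1, measure_vessels(fx$pair))
})
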