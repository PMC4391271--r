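# Classification module: conductivity criteria and xylem-type assignment.

test_that("the bright-field criterion requires a complete wall and maturity", {
  expect_true(classify_bf(1.0, FALSE))
  expect_false(classify_bf(0.95, TRUE))     # expanding vessels are excluded
  expect_false(classify_bf(0.75, FALSE))
  expect_equal(classify_bf(c(0.95, 0.85), c(FALSE, FALSE)), c(TRUE, FALSE))
  expect_error(classify_bf(0.9, FALSE, theta_bf = 0), "theta_bf")
  expect_error(classify_bf(1.2, FALSE), "wall_completeness")
})

test_that("the epifluorescence criterion is strictly more-than-half", {
  expect_true(classify_ef(0.51))
  expect_false(classify_ef(0.50))
  expect_false(classify_ef(0))
  expect_error(classify_ef(1.3), "stain_fraction")
})

test_that("expanding vessels are the large unwalled ones", {
  rec <- data.frame(
    area_um2 = c(80, 120, 200, 15, 60),
    wall_completeness = c(1, 1, 0.6, 0.3, 0.5))
  fl <- flag_expanding(rec)
  expect_equal(fl, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # fully walled table: nothing flagged
  expect_false(any(flag_expanding(data.frame(area_um2 = c(10, 400),
                                             wall_completeness = c(1, 0.95)))))
})

test_that("xylem types round-trip through rendering on a single bundle", {
  cfg <- small_config(seed = 5, noise_sd = 0)
  tr <- build_ground_truth(cfg)
  rec <- classify_all(measure_vessels(render_pair(tr, cfg)))
  idx <- match_vessels(rec, tr)
  expect_true(all(!is.na(idx)))
  expect_equal(rec$type, tr$type[idx])
})

test_that("isolated vessels fall back to the diameter cutoff", {
  one_big <- data.frame(centroid_x_um = 50, centroid_y_um = 50,
                        area_um2 = pi * 9^2, diameter_um = 18,
                        wall_completeness = 1, stain_fraction = 0.8)
  expect_equal(assign_xylem_type(one_big), "MX")
  one_small <- transform(one_big, diameter_um = 5, area_um2 = pi * 2.5^2)
  expect_equal(assign_xylem_type(one_small), "PX")
})

test_that("classification is idempotent and the EF set is nested in the BF set", {
  segs <- generate_cohort(2, small_config("apical", 3),
                          small_config("basal", 3), seed = 21, render = FALSE)
  for (s in segs) {
    rec <- classify_all(xylemtrace:::truth_records(s$truth, s$config))
    expect_identical(rec, classify_all(rec))
    expect_true(all(!rec$conductive_ef | rec$conductive_bf))
  }
})

test_that("an all-stained table is entirely EF-conductive", {
  rec <- data.frame(centroid_x_um = c(10, 30, 60), centroid_y_um = 10,
                    area_um2 = pi * c(4, 5, 8)^2,
                    diameter_um = c(8, 10, 16),
                    wall_completeness = 1,
                    stain_fraction = c(0.9, 0.8, 0.95))
  out <- classify_all(rec)
  expect_true(all(out$conductive_ef))
  expect_true(all(out$conductive_bf))
})
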