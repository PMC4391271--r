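# Hydraulics module: flow-rate estimation and conductivity arithmetic.

test_that("flow-rate estimation fits the steady window and rejects transients", {
  t <- seq(0, 1800, by = 20)
  lin <- flow_trace(t, 1e-4 * t, 0.04, 0.03, 1000)
  expect_equal(estimate_flow_rate(lin), 1e-10, tolerance = 1e-12)
  # exponential start-up confined to the first half leaves the fit untouched
  tau <- 60
  trans <- flow_trace(t, 1e-4 * (t - tau * (1 - exp(-t / tau))),
                      0.04, 0.03, 1000)
  expect_equal(estimate_flow_rate(trans), 1e-10, tolerance = 1e-6)
  expect_error(estimate_flow_rate(lin, window_fraction = 0.02), "3 samples")
  flat <- flow_trace(t, rep(0, length(t)), 0.04, 0.03, 1000)
  expect_error(estimate_flow_rate(flat), "no positive steady flow")
})

test_that("flow traces validate their structure", {
  expect_error(flow_trace(c(0, 20), c(0, 1), 0.04, 0.03), "3 samples")
  expect_error(flow_trace(c(0, 40, 20), c(0, 1, 2), 0.04, 0.03),
               "strictly increasing")
  expect_error(flow_trace(c(0, 20, 40), c(0, 1, 2), -1, 0.03),
               "pressure_gradient")
})

test_that("experimental conductivity follows F L / dP", {
  expect_equal(compute_kh(1e-10, 0.03, 0.04), 7.5e-11, tolerance = 1e-15)
  expect_equal(compute_kh(1e-10, 0.03, 0.08) * 2, compute_kh(1e-10, 0.03, 0.04))
  expect_equal(compute_kh(2e-10, 0.03, 0.04) / compute_kh(1e-10, 0.03, 0.04), 2)
  expect_error(compute_kh(0, 0.03, 0.04), "> 0")
})

test_that("equivalent diameter inverts the circular area", {
  expect_equal(diameter_from_area(78.5398), 10, tolerance = 1e-4)
  expect_equal(diameter_from_area(pi), 2, tolerance = 1e-12)
  d <- c(3.7, 9.2, 21.4)
  expect_equal(diameter_from_area(pi * (d / 2)^2), d, tolerance = 1e-12)
  expect_error(diameter_from_area(-1), "area")
})

test_that("the Hagen-Poiseuille sum matches its closed form, scales quartically and adds", {
  expect_identical(compute_kht(numeric(0)), 0)
  expect_equal(compute_kht(10), pi * 1e-20 / (128 * 1.002e-9),
               tolerance = 1e-12)
  expect_lt(abs(compute_kht(10) - 2.4495e-13), 1e-16)
  expect_equal(compute_kht(20) / compute_kht(10), 16, tolerance = 1e-12)
  a <- c(7.3, 11.8); b <- c(15.1, 9.9, 24)
  expect_equal(compute_kht(c(a, b)), compute_kht(a) + compute_kht(b),
               tolerance = 1e-12)
  expect_error(compute_kht(c(10, -2)), "index 2")
})

test_that("specific conductivity, relative contribution and resistivity are consistent", {
  expect_equal(specific_conductivity(7.5e-11, 5e-8), 1.5e-3)
  expect_equal(specific_conductivity(7.5e-11, 1e-7) * 2,
               specific_conductivity(7.5e-11, 5e-8))
  expect_equal(specific_conductivity(0, 5e-8), 0)
  expect_equal(relative_contribution(1e-10, 1e-10), 100)
  expect_equal(relative_contribution(3.41e-11, 1.11e-10), 30.72,
               tolerance = 1e-3)
  expect_equal(relative_contribution(0, 1e-10), 0)
  expect_error(relative_contribution(1e-11, 0), "kht")
  expect_equal(resistivity(5e-10), 2e9)
  expect_equal(resistivity(resistivity(3.7)), 3.7)
  expect_equal(resistivity(2.5e-11) * 0.5, resistivity(5e-11))
  expect_error(resistivity(0), "kh")
})

test_that("segment summaries split conductivities by criterion", {
  rec <- data.frame(
    centroid_x_um = c(10, 40, 80, 120), centroid_y_um = 10,
    area_um2 = pi * c(5, 6, 8, 4)^2,
    diameter_um = c(10, 12, 16, 8),
    wall_completeness = c(1, 1, 1, 0.6),
    stain_fraction = c(0.9, 0.3, 0.8, 0.1))
  rec <- classify_all(rec)
  t <- seq(0, 1800, by = 20)
  trace <- flow_trace(t, 1e-4 * t, 0.04, 0.03, 1000)
  s <- summarize_segment(rec, trace)
  expect_equal(s$kh, 7.5e-11, tolerance = 1e-12)
  expect_equal(s$kht_bf, compute_kht(c(10, 12, 16)), tolerance = 1e-14)
  expect_equal(s$kht_ef, compute_kht(c(10, 16)), tolerance = 1e-14)
  expect_lte(s$kht_ef, s$kht_bf)
  expect_equal(s$ratio_ef, 100 * s$kh / s$kht_ef, tolerance = 1e-12)

  # identical calls -> identical conductivities
  rec2 <- transform(rec, stain_fraction = 0.9)
  rec2 <- classify_all(rec2)
  s2 <- summarize_segment(rec2, trace)
  expect_equal(s2$kht_bf, s2$kht_ef)

  # no EF-conductive vessels -> zero Kht, missing specific conductivity
  rec3 <- transform(rec, stain_fraction = 0.2)
  rec3 <- classify_all(rec3)
  s3 <- summarize_segment(rec3, trace)
  expect_equal(s3$kht_ef, 0)
  expect_true(is.na(s3$khts_ef))
  expect_true(is.na(s3$ratio_ef))
})
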