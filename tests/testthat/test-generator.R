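# Synthetic-data module: ground truth, rendering, flow traces, cohorts.

test_that("zero vessel counts give an empty truth and a pure-background render", {
  cfg <- generator_config("apical", seed = 3, pixel_size = 0.25,
                          image_shape = c(200L, 200L), n_bundles = 1,
                          ring_radius = 0, px_count_mean = 0,
                          mx_count_mean = 0, fiber_density = 10, noise_sd = 0)
  tr <- build_ground_truth(cfg)
  expect_equal(nrow(tr), 0L)
  pair <- render_pair(tr, cfg)
  expect_lt(diff(range(pair$bf)), 1e-3)   # flat background
  expect_identical(detect_lumens(pair$bf, cfg$pixel_size), list())
})

test_that("identical config and seed reproduce truth, images and traces bit for bit", {
  cfg <- small_config(seed = 11)
  t1 <- build_ground_truth(cfg); t2 <- build_ground_truth(cfg)
  expect_identical(t1, t2)
  p1 <- render_pair(t1, cfg); p2 <- render_pair(t2, cfg)
  expect_identical(p1$bf, p2$bf)
  expect_identical(p1$ef, p2$ef)
  f1 <- synthesize_flow_trace(5e-11, cfg, seed = 4)
  f2 <- synthesize_flow_trace(5e-11, cfg, seed = 4)
  expect_identical(f1$cumulative_mass_g, f2$cumulative_mass_g)
})

test_that("realized vessel counts match the configured means, with plant-level dispersion", {
  cfg <- generator_config("basal", seed = 1)
  n_px <- n_mx <- numeric(200)
  for (k in 1:200) {
    tr <- build_ground_truth(cfg, seed = k)
    n_px[k] <- sum(tr$type == "PX")
    n_mx[k] <- sum(tr$type == "MX")
  }
  expect_lt(abs(mean(n_px) - cfg$px_count_mean), 3 * sd(n_px) / sqrt(200))
  expect_lt(abs(mean(n_mx) - cfg$mx_count_mean), 3 * sd(n_mx) / sqrt(200))
  # stems vary in vigour: counts are strongly overdispersed beyond Poisson
  expect_gt(sd(n_px), 1.3 * sqrt(cfg$px_count_mean))
  expect_gt(sd(n_mx), 2.0 * sqrt(cfg$mx_count_mean))
})

test_that("the lignified-but-nonconductive fraction matches its configured mean", {
  cfg <- generator_config("basal", seed = 1,
                          frac_walled_nonconductive = 0.35,
                          frac_expanding = 0)
  frac <- numeric(200)
  for (k in 1:200) {
    tr <- build_ground_truth(cfg, seed = 5000 + k)
    full <- tr$wall_state == "full"
    frac[k] <- sum(full & !tr$conductive) / sum(full)
  }
  # each segment draws its own maturation state around the configured mean
  expect_lt(abs(mean(frac) - 0.35), 3 * sd(frac) / sqrt(200))
  # a fixed fraction is recovered exactly in expectation too
  cfg2 <- generator_config("basal", seed = 1,
                           frac_walled_nonconductive = 0.35,
                           frac_nonconductive_concentration = Inf,
                           frac_expanding = 0)
  walled <- noncond <- 0
  for (k in 1:60) {
    tr <- build_ground_truth(cfg2, seed = 7000 + k)
    full <- tr$wall_state == "full"
    walled <- walled + sum(full)
    noncond <- noncond + sum(full & !tr$conductive)
  }
  expect_lt(abs(noncond / walled - 0.35), 3 * sqrt(0.35 * 0.65 / walled))
})

test_that("ground truth satisfies its class invariants across seeds", {
  for (seed in c(2, 17, 33)) {
    for (st in c("apical", "basal")) {
      cfg <- generator_config(st, seed = seed)
      tr <- build_ground_truth(cfg)
      expect_true(all(!tr$conductive |
                        (tr$wall_state == "full" & tr$stain_fraction > 0.5)))
      expect_true(all(tr$wall_state == "full" |
                        (!tr$conductive & tr$stain_fraction <= 0.5)))
      # no overlap: centre distances exceed summed radii + wall allowance
      d <- as.matrix(dist(cbind(tr$x_um, tr$y_um)))
      lim <- outer(tr$diameter_um / 2 + cfg$wall_width,
                   tr$diameter_um / 2 + cfg$wall_width, "+")
      diag(d) <- Inf
      expect_true(all(d > lim))
    }
  }
})

test_that("vessel_truth rejects invariant violations", {
  expect_error(vessel_truth(10, 10, 8, "partial", stain_fraction = 0.8,
                            conductive = TRUE),
               "conductive")
  expect_error(vessel_truth(10, 10, 8, "absent", stain_fraction = 0.7),
               "incompletely walled")
  expect_error(vessel_truth(c(10, 14), 10, 8), "overlap")
})

test_that("a noise-free transient-free trace is exactly linear with the predicted slope", {
  cfg <- generator_config("basal", seed = 1, balance_noise_sd = 0,
                          transient_tau = 0, water_density = 1000)
  tr <- synthesize_flow_trace(7.5e-11, cfg, seed = 1)
  slopes <- diff(tr$cumulative_mass_g) / diff(tr$time_s)
  expect_equal(slopes, rep(1e-4, length(slopes)), tolerance = 1e-12)
  expect_equal(estimate_flow_rate(tr), 1e-10, tolerance = 1e-12)
  expect_equal(compute_kh(estimate_flow_rate(tr), 0.03, 0.04), 7.5e-11,
               tolerance = 1e-12)
})

test_that("doubling the conductivity doubles the fitted slope", {
  cfg <- generator_config("basal", seed = 1, balance_noise_sd = 0)
  f1 <- estimate_flow_rate(synthesize_flow_trace(4e-11, cfg, seed = 2))
  f2 <- estimate_flow_rate(synthesize_flow_trace(8e-11, cfg, seed = 2))
  expect_equal(f2 / f1, 2, tolerance = 1e-9)
})

test_that("flow-rate estimation recovers the true rate from noisy traces", {
  cfg <- generator_config("basal", seed = 1)
  kh <- 3.41e-11
  errs <- vapply(1:20, function(s) {
    tr <- synthesize_flow_trace(kh, cfg, seed = s)
    est <- compute_kh(estimate_flow_rate(tr), cfg$segment_length,
                      cfg$pressure_gradient)
    abs(est - kh) / kh
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("trace synthesis validates its inputs", {
  cfg <- generator_config("basal", seed = 1, duration = 30)
  expect_error(synthesize_flow_trace(1e-11, cfg), "3 sampling intervals")
  expect_error(synthesize_flow_trace(0, generator_config("basal")), "> 0")
})

test_that("infeasible placement names the offending bundle", {
  cfg <- generator_config("basal", seed = 1, image_shape = c(300L, 300L),
                          ring_radius = 10, n_bundles = 1,
                          px_count_mean = 200, mx_count_mean = 0)
  expect_error(build_ground_truth(cfg), "bundle 1")
})

test_that("rendering a vessel outside the image names the vessel", {
  cfg <- generator_config("apical", seed = 1, image_shape = c(100L, 100L),
                          n_bundles = 1, ring_radius = 0,
                          px_count_mean = 0, mx_count_mean = 0)
  tr <- vessel_truth(2, 12, 10)
  expect_error(render_pair(tr, cfg), "vessel 1")
})

test_that("a cohort pairs one apical and one basal segment per plant, reproducibly", {
  ca <- small_config("apical"); cb <- small_config("basal")
  segs <- generate_cohort(2, ca, cb, seed = 9, render = FALSE)
  expect_length(segs, 4L)
  expect_equal(vapply(segs, `[[`, "", "segment_type"),
               rep(c("apical", "basal"), 2))
  expect_equal(vapply(segs, `[[`, 0, "plant"), c(1, 1, 2, 2))
  segs2 <- generate_cohort(2, ca, cb, seed = 9, render = FALSE)
  expect_identical(lapply(segs, `[[`, "truth"), lapply(segs2, `[[`, "truth"))
  for (s in segs) {
    expect_gt(s$true_kh, 0)
    expect_lte(s$true_kh, s$true_kht)
    expect_equal(s$true_kht, compute_kht(s$truth$diameter_um[s$truth$conductive]),
                 tolerance = 1e-14)
  }
})

test_that("drawn efficiencies match the configured truncated-lognormal mean", {
  pars <- xylemtrace:::calibrate_efficiency(0.33, 0.69)
  set.seed(42)
  e <- xylemtrace:::draw_efficiency(pars, 500)
  expect_true(all(e > 0 & e <= 1))
  expect_lt(abs(mean(e) - 0.33), 3 * sd(e) / sqrt(500))
})
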