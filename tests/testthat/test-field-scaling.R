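test_that("creekhead areal coverage scales density by the creekhead footprint", {
  # regional survey value: 110.2 creeks/km^2 * 0.0025 km^2 -> 27.55 %,
  # printed as 27.6 %
  expect_equal(creekhead_areal_coverage(110.2), 27.55, tolerance = 1e-12)
  expect_equal(round(creekhead_areal_coverage(110.2), 1), 27.6)
  expect_identical(creekhead_areal_coverage(0), 0)
  expect_equal(creekhead_areal_coverage(400), 100)
  expect_error(creekhead_areal_coverage(-1))
})

test_that("creekshed mussel coverage is the creekhead-cover x mussel-fraction product", {
  expect_equal(round(creekshed_mussel_coverage(27.6, 0.103), 1), 2.8)
  expect_equal(creekshed_mussel_coverage(55, 0), 0)
  expect_equal(creekshed_mussel_coverage(100, 0.5), 50)
  expect_error(creekshed_mussel_coverage(150, 0.5))
})

test_that("platform elevation from mound heights inverts the growth ceiling", {
  r <- platform_elevation_from_mounds(c(0.081, 0))
  expect_equal(r$elevation, c(0.759, 0.84))
  # permutation invariance of the mean
  h <- c(0.05, 0.11, 0.083, 0.002, 0.09)
  expect_equal(platform_elevation_from_mounds(h)$mean,
               platform_elevation_from_mounds(rev(h))$mean)
  # creek-level mean is the mean of transect means, not the pooled mean
  df <- data.frame(height_m = c(0.10, 0.10, 0.10, 0.30),
                   transect = c("t0", "t0", "t0", "t20"),
                   creek = "control")
  r2 <- platform_elevation_from_mounds(df)
  expect_equal(r2$by_creek$mean_elevation, mean(c(0.84 - 0.10, 0.84 - 0.30)))
  # implausible heights flagged, not dropped
  r3 <- platform_elevation_from_mounds(c(0.1, 2.5))
  expect_identical(r3$outliers, 2L)
})

test_that("deposition-to-accretion conversion is a transparent linear calculator", {
  r <- deposition_to_accretion(1e-3, 0.8, 1)
  expect_equal(r$accretion_cm_yr, 1e-3 / 0.8 * 365.25, tolerance = 1e-12)
  expect_equal(deposition_to_accretion(2e-3)$accretion_cm_yr,
               2 * deposition_to_accretion(1e-3)$accretion_cm_yr)
  expect_equal(deposition_to_accretion(0)$accretion_cm_yr, 0)
  # halving the flooded fraction halves the rate
  expect_equal(deposition_to_accretion(1e-3, flooding_factor = 0.5)$accretion_cm_yr,
               deposition_to_accretion(1e-3)$accretion_cm_yr / 2)
})

test_that("settling-velocity fit recovers known parameters on noiseless decay", {
  for (ws_true in c(5e-5, 1e-4, 8e-4)) {
    s <- gen_tss_series(ws = ws_true, h = 0.30, c_s0 = 0.10, noise_sd = 0)
    fit <- fit_settling_velocity(s, h = 0.30, c_s0 = 0.10)
    expect_equal(fit$ws, ws_true, tolerance = 1e-6)
    expect_lt(fit$rmse, 1e-6)
    # co-estimated initial concentration also recovers
    fit2 <- fit_settling_velocity(s, h = 0.30)
    expect_equal(fit2$ws, ws_true, tolerance = 1e-6)
    expect_equal(fit2$c_s0, 0.10, tolerance = 1e-6)
  }
})

test_that("settling-velocity fit agrees with a dense grid-search oracle", {
  set.seed(42)
  for (k in 1:50) {
    ws_true <- exp(runif(1, log(2e-5), log(2e-3)))
    s <- gen_tss_series(ws = ws_true, h = 0.30, c_s0 = runif(1, 0.05, 0.2),
                        noise_sd = 0.005, n_points = 20, seed = 1000 + k)
    fit <- fit_settling_velocity(s, h = 0.30)
    oracle <- grid_search_ws(s, h = 0.30)
    expect_equal(fit$ws, oracle, tolerance = 0.01)
  }
})

test_that("noisy-series recovery sits inside Monte-Carlo bounds", {
  ws_true <- 1e-4
  ests <- vapply(1:200, function(k) {
    s <- gen_tss_series(ws = ws_true, h = 0.30, c_s0 = 0.10,
                        noise_sd = 0.01, seed = k)
    fit_settling_velocity(s, h = 0.30, c_s0 = 0.10)$ws
  }, 0)
  # the estimator is approximately unbiased at this noise level ...
  expect_lt(abs(mean(ests) - ws_true) / ws_true, 0.05)
  # ... and a fresh fixed-seed draw falls inside the simulated spread
  s <- gen_tss_series(ws = ws_true, h = 0.30, c_s0 = 0.10,
                      noise_sd = 0.01, seed = 777)
  est <- fit_settling_velocity(s, h = 0.30, c_s0 = 0.10)$ws
  expect_gt(est, mean(ests) - 4 * sd(ests))
  expect_lt(est, mean(ests) + 4 * sd(ests))
})

test_that("degenerate fit inputs are rejected", {
  s <- gen_tss_series()
  s$conc_kg_m3[] <- 0
  expect_error(fit_settling_velocity(s), "zero")
  expect_error(fit_settling_velocity(gen_tss_series(n_points = 3)[1:2, ]))
})
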