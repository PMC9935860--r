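test_that("vegetated Chezy follows the emergent/submerged formulation", {
  # bare bed returns the unvegetated coefficient
  expect_equal(chezy_vegetated(0.5, n = 0, h_v = 0), 45)
  # hand evaluation of the emergent branch
  g <- 9.81
  c_hand <- 1 / sqrt(1 / 45^2 + 1.65 * 5 * 0.3 / (2 * g))
  expect_equal(chezy_vegetated(0.3, n = 5, h_v = 0.4), c_hand, tolerance = 1e-12)
  # continuity at h = h_v
  expect_equal(chezy_vegetated(0.4, n = 5, h_v = 0.4),
               chezy_vegetated(0.4 + 1e-9, n = 5, h_v = 0.4), tolerance = 1e-6)
  # hand evaluation of the submerged branch
  c_sub <- 1 / sqrt(1 / 45^2 + 1.65 * 5 * 0.4 / (2 * g)) +
    sqrt(g) / 0.41 * log(0.8 / 0.4)
  expect_equal(chezy_vegetated(0.8, n = 5, h_v = 0.4), c_sub, tolerance = 1e-12)
  # denser canopy -> rougher (smaller C); deeper submergence -> smoother
  expect_lt(chezy_vegetated(0.3, n = 10, h_v = 0.4),
            chezy_vegetated(0.3, n = 5, h_v = 0.4))
  expect_gt(chezy_vegetated(2.0, n = 5, h_v = 0.4),
            chezy_vegetated(0.5, n = 5, h_v = 0.4))
  expect_error(chezy_vegetated(0, n = 5, h_v = 0.4))
})

test_that("bed shear stress is quadratic in speed and zero at rest", {
  expect_equal(bed_shear(0, 0, 45), 0)
  expect_equal(bed_shear(0.3, 0, 45), 1025 * 9.81 * 0.09 / 45^2,
               tolerance = 1e-12)
  expect_equal(bed_shear(0.6, 0, 45), 4 * bed_shear(0.3, 0, 45))
  expect_equal(bed_shear(0.3, 0.4, 45), bed_shear(0.5, 0, 45))
  expect_equal(bed_shear(1, 0, 45, wet = FALSE), 0)
})

test_that("implicit filtration sink removes mass without going negative", {
  bp <- suppressWarnings(bivalve_params(f_mm = 0.115, f_mm_unit = "per_second"))
  # printed-parameter example: C_new = C / (1 + 177*0.115*0.6/0.5)
  r <- filtration_sink(0.05, h = 0.5, params = bp, dt = 0.6)
  expect_equal(r$c_new, 0.05 / (1 + 177 * 0.115 * 0.6 / 0.5), tolerance = 1e-12)
  expect_equal(r$c_new, 1.97e-3, tolerance = 0.01)
  # removed mass equals the concentration drop times the column depth
  expect_equal(r$filtered_mass, (0.05 - r$c_new) * 0.5, tolerance = 1e-15)
  # no mussels: no-op
  r0 <- filtration_sink(0.05, 0.5, bp, 0.6, rho_mm_eff = 0)
  expect_equal(r0$c_new, 0.05)
  expect_equal(r0$filtered_mass, 0)
  # saturation: cannot over-filter the column
  rs <- filtration_sink(0.05, 0.5, bp, dt = 1e9)
  expect_lt(rs$c_new, 1e-10)
  expect_equal(rs$filtered_mass, 0.05 * 0.5, tolerance = 1e-6)
  # dry cell: untouched
  rd <- filtration_sink(0.05, h = 0.001, params = bp, dt = 0.6)
  expect_equal(rd$c_new, 0.05)
  # never negative for any random parameter draw
  set.seed(9)
  for (k in 1:100) {
    rr <- filtration_sink(runif(1, 0, 1), runif(1, 0.02, 3),
                          bivalve_params(rho_mm = runif(1, 1, 1e4),
                                         f_mm = runif(1, 1e-3, 10),
                                         f_mm_unit = sample(c("per_day", "per_hour"), 1)),
                          dt = runif(1, 0.1, 100))
    expect_gte(rr$c_new, 0)
    expect_gte(rr$filtered_mass, 0)
  }
})

test_that("biodeposition matches the explicit small-dt form and conserves mass", {
  # explicit limit of the printed deposition increment:
  # rho_MM * f_MM * C * dt / rho_dry with the printed per-second unit
  dz_explicit <- 177 * 0.115 * 0.1 * 0.6 / 800
  expect_equal(dz_explicit, 1.527e-3, tolerance = 1e-3)
  # the implicit update approaches it as dt -> 0 (first order)
  bp <- suppressWarnings(bivalve_params(f_mm = 0.115, f_mm_unit = "per_second"))
  h <- 20.3551   # deep column so the per-step removal stays small
  n <- 600
  c0 <- 0.1
  dz <- 0
  cc <- c0
  for (k in 1:n) {
    r <- filtration_sink(cc, h, bp, dt = 0.6 / n)
    dz <- dz + biodeposit(r$filtered_mass)
    cc <- r$c_new
  }
  # compare against the exact integral of the decaying concentration
  kf <- 177 * 0.115 / h
  dz_exact <- c0 * h * (1 - exp(-kf * 0.6)) / 800
  expect_equal(dz, dz_exact, tolerance = 1e-3)
  expect_equal(biodeposit(0), 0)
  # ledger identity: filtered mass re-emerges as bed volume times density
  expect_equal(dz * 800, (c0 - cc) * h, tolerance = 1e-12)
})

test_that("filtration is supply-limited at the printed per-second rate", {
  # with rho*f*dt/h >> 1 deposition tracks delivery, not the filtration
  # rate: doubling f_mm changes the filtered mass by < 5 %
  b1 <- suppressWarnings(bivalve_params(f_mm = 0.115, f_mm_unit = "per_second"))
  b2 <- suppressWarnings(bivalve_params(f_mm = 0.230, f_mm_unit = "per_second"))
  m1 <- filtration_sink(0.05, 0.5, b1, dt = 0.6)$filtered_mass
  m2 <- filtration_sink(0.05, 0.5, b2, dt = 0.6)$filtered_mass
  expect_lt((m2 - m1) / m1, 0.05)
})

test_that("per-mound budget aggregates the process ledger", {
  d <- gen_mini_domain(cover = 0.10)
  fake <- list(dz_settling = matrix(1e-3, d$n_rows, d$n_cols),
               dz_filtration = matrix(2e-3, d$n_rows, d$n_cols),
               dz_erosion = matrix(-1e-4, d$n_rows, d$n_cols),
               accretion_cm_yr = matrix(1, d$n_rows, d$n_cols))
  b <- mound_budget(fake, d)
  expect_equal(nrow(b), sum(d$mound_frac > 0))
  expect_equal(b$dz_total_m, rep(2.9e-3, nrow(b)))
  # totals match the ledger summed over mound cells
  expect_equal(sum(b$dz_filtration_m),
               sum(fake$dz_filtration[d$mound_frac > 0]))
  empty <- mound_budget(fake, gen_mini_domain(cover = 0))
  expect_equal(nrow(empty), 0)
})

test_that("the per-second unit flag warns about the implausible clearance rate", {
  expect_warning(bivalve_params(f_mm = 0.115, f_mm_unit = "per_second"),
                 "implausible")
  expect_silent(bivalve_params(f_mm = 0.115, f_mm_unit = "per_day"))
  expect_equal(bivalve_params(f_mm = 0.115, f_mm_unit = "per_day")$f_mm_si,
               0.115 / 86400)
})
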