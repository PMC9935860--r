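test_that("quiescent settling reproduces the exponential decay law", {
  # still closed column: C(t) = C0 exp(-t ws / h)
  f <- flume_domain(n_rows = 5, n_cols = 1, cell = 1, slope = 0, zb0 = 0)
  h <- 0.3; ws <- 1e-4; c0 <- 0.1
  t_fold <- h / ws
  s <- step_sediment(f, h, duration = t_fold, dt = 0.5,
                     params = sediment_params(ws = ws, c_boundary = 0,
                                              diffusivity = 0),
                     state = list(conc = matrix(c0, 5, 1)))
  expect_equal(s$conc[3, 1], c0 * exp(-1), tolerance = 0.01)
  # deposited depth balances the mass lost from suspension
  expect_equal(s$dz_settling[3, 1] * 800, (c0 - s$conc[3, 1]) * h,
               tolerance = 1e-6)
})

test_that("pure transport conserves suspended mass in a closed domain", {
  f <- flume_domain(n_rows = 30, n_cols = 4, cell = 1, slope = 0, zb0 = -2)
  conc0 <- matrix(0, 30, 4); conc0[10:12, 2] <- 0.2
  lev <- 0.5 + 0.3 * sin(2 * pi * seq(0, 7200, 60) / 3600)  # slosh it around
  s <- step_sediment(f, lev, 3600, dt = 0.5, bc_dt = 60,
                     params = sediment_params(ws = 0, c_boundary = 0,
                                              diffusivity = 0.2),
                     state = list(conc = conc0))
  total0 <- sum(conc0 * s$h * 0)  # initial depth differs; use ledger instead
  expect_lt(s$max_mass_resid, 1e-9)
  expect_equal(sum(s$dz_settling) + sum(s$dz_filtration), 0)
  # mass still in suspension + net export equals the initial load
  m0 <- sum(conc0 * 2.5)          # h = 0.5 - (-2) = 2.5 everywhere initially
  expect_equal(s$suspended_kg + s$sed_out - s$sed_in, m0, tolerance = 1e-6)
})

test_that("a point release advects at the flow speed and spreads at 2Kt", {
  # steady uniform flow (Chezy balance), then a tracer blob
  S <- 1e-4; L <- 300; h0 <- 1; K <- 0.2
  f <- flume_domain(n_rows = L, n_cols = 1, cell = 1, slope = S, zb0 = -2)
  eta_sea <- -1; eta_land <- -1 + S * L
  spin <- step_flow(f, eta_sea, duration = 4000, dt = 0.5,
                    land_level = eta_land, advection = FALSE, viscosity = 0)
  u <- mean(abs(spin$v[100:200, 1]))
  expect_gt(u, 0.3)
  y <- f$y_center
  conc0 <- matrix(dnorm(y, mean = 60, sd = 3), L, 1)
  dt <- 0.25
  stride <- max(1L, round(0.98 * 1 / (u * dt)))   # sediment Courant ~ 0.98
  TT <- 300
  s <- step_sediment(f, eta_sea, duration = TT, dt = dt,
                     land_level = eta_land, advection = FALSE, viscosity = 0,
                     params = sediment_params(ws = 0, c_boundary = 0,
                                              diffusivity = K),
                     state = list(eta = spin$eta, u = spin$u, v = spin$v,
                                  conc = conc0),
                     sed_stride = stride)
  m <- s$conc[, 1]
  cen <- sum(y * m) / sum(m)
  v2 <- sum((y - cen)^2 * m) / sum(m)
  # flow runs seaward (down-slope): centroid moves -u * T
  expect_equal(cen, 60 - u * TT, tolerance = 0.05 * u * TT)
  expect_equal(v2, 9 + 2 * K * TT, tolerance = 0.05 * (9 + 2 * K * TT))
})

test_that("boundary inflow carries the prescribed concentration on flood only", {
  d <- gen_mini_domain()
  lev <- seq(0.3, 1.2, length.out = 61)  # rising tide only
  s <- step_sediment(d, lev, 3600, dt = 0.5, bc_dt = 60,
                     params = sediment_params(c_boundary = 0.05))
  expect_gt(s$sed_in, 0)
  expect_lt(s$sed_out, s$sed_in)
  expect_true(all(s$conc >= 0))
  expect_true(all(s$conc <= 0.05 + 1e-9))
  # no boundary supply -> nothing deposits
  s0 <- step_sediment(d, lev, 3600, dt = 0.5, bc_dt = 60,
                      params = sediment_params(c_boundary = 0))
  expect_equal(sum(s0$dz_settling), 0)
})

test_that("deposition responds exactly linearly to the boundary concentration", {
  d <- gen_mini_domain()
  tt <- seq(0, 13 * 3600, 60)
  lev <- 0.3 + 1.2 * sin(2 * pi * tt / (12.42 * 3600))
  s1 <- step_sediment(d, lev, 4 * 3600, dt = 0.5, bc_dt = 60,
                      params = sediment_params(c_boundary = 0.05))
  s2 <- step_sediment(d, lev, 4 * 3600, dt = 0.5, bc_dt = 60,
                      params = sediment_params(c_boundary = 0.10))
  expect_equal(s2$dz_settling, 2 * s1$dz_settling, tolerance = 1e-12)
  expect_equal(s2$dz_filtration, 2 * s1$dz_filtration, tolerance = 1e-12)
})

test_that("the full sediment-mass ledger closes through a tidal cycle", {
  run <- mini_run()
  expect_lt(run$state$max_mass_resid, 1e-9)
  expect_equal(run$state$clamp_mass_kg, 0)
  # suspended + bed - net import = 0 (initial load was zero), recomputed
  st <- run$state
  bed <- sum((st$dz_settling + st$dz_filtration + st$dz_erosion) * 800 *
               run$domain$cell_area)
  expect_equal(st$suspended_kg + bed, st$sed_in - st$sed_out,
               tolerance = 1e-6)
})

test_that("mound erosion obeys the threshold, the cap and the hand integral", {
  d <- gen_mini_domain()
  mound <- d$mound_frac > 0
  ledger <- list(dz_settling = matrix(1e-4, d$n_rows, d$n_cols),
                 dz_filtration = matrix(1e-4, d$n_rows, d$n_cols),
                 dz_erosion = matrix(0, d$n_rows, d$n_cols))
  conc <- matrix(0.01, d$n_rows, d$n_cols)
  h <- matrix(0.5, d$n_rows, d$n_cols)
  p <- sediment_params(tau_ce = 1, m_erod = 1e-4)
  # below threshold: no change anywhere
  tau_lo <- matrix(0.8, d$n_rows, d$n_cols)
  r <- erode_mounds(ledger, conc, h, tau_lo, p, mound, dt = 10)
  expect_identical(r$conc, conc)
  expect_identical(r$dz_erosion, ledger$dz_erosion)
  # steady tau = 2 N/m^2: eroded depth = M (tau/tau_ce - 1) t / rho_dry
  tau_hi <- matrix(2, d$n_rows, d$n_cols)
  r2 <- erode_mounds(ledger, conc, h, tau_hi, p, mound, dt = 100)
  dz_hand <- 1e-4 * (2 / 1 - 1) * 100 / 800
  expect_equal(unique(-r2$dz_erosion[mound]), dz_hand, tolerance = 1e-12)
  expect_true(all(r2$dz_erosion[!mound] == 0))
  # cap: cannot erode more than was deposited
  r3 <- erode_mounds(ledger, conc, h, tau_hi, p, mound, dt = 1e9)
  expect_true(all(-r3$dz_erosion[mound] <=
                    ledger$dz_settling[mound] + ledger$dz_filtration[mound] + 1e-15))
  # resuspended mass returns to the water column
  expect_equal((r2$conc - conc)[mound] * 0.5,
               -(r2$dz_erosion[mound]) * 800, tolerance = 1e-12)
})

test_that("in-solver resuspension spreads mound deposits and stays conserving", {
  d <- gen_mini_domain()
  tt <- seq(0, 13 * 3600, 60)
  lev <- 0.3 + 1.2 * sin(2 * pi * tt / (12.42 * 3600))
  s <- step_sediment(d, lev, 12.42 * 3600, dt = 0.5, bc_dt = 60,
                     erosion = TRUE,
                     params = sediment_params(tau_ce = 0.001, m_erod = 1e-3))
  expect_true(all(s$dz_erosion <= 0))
  expect_lt(sum(s$dz_erosion), 0)     # with a tiny threshold, something erodes
  expect_lt(s$max_mass_resid, 1e-9)
})

test_that("accretion annualisation uses the cycles-per-year factor", {
  d <- gen_mini_domain()
  st <- list(dz_settling = matrix(1e-3, d$n_rows, d$n_cols),
             dz_filtration = matrix(0, d$n_rows, d$n_cols),
             dz_erosion = matrix(0, d$n_rows, d$n_cols))
  ann <- accretion_rate(st, d, duration = 16 * 86400)
  # 1 mm per 16-day cycle -> 0.1 cm x 365.25/16 = 2.283 cm/yr
  expect_equal(unique(as.vector(ann$accretion_cm_yr)), 2.283, tolerance = 1e-3)
  expect_equal(ann$annual_factor, 365.25 / 16, tolerance = 1e-12)
  expect_equal(sum(ann$deposition_m3_yr),
               1e-3 * sum(d$cell_area) * 365.25 / 16, tolerance = 1e-9)
  zero <- accretion_rate(list(dz_settling = matrix(0, d$n_rows, d$n_cols),
                              dz_filtration = matrix(0, d$n_rows, d$n_cols),
                              dz_erosion = matrix(0, d$n_rows, d$n_cols)),
                         d, duration = 16 * 86400)
  expect_true(all(zero$accretion_cm_yr == 0))
})
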