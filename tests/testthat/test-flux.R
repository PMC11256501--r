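test_that("ideal-gas ppm-to-mass conversion is exact, linear and guarded", {
  ## hand evaluation: 2 ppm in a 1.5 L jar at 1 atm, 300.15 K
  expect_equal(ppm_to_mass(2, 1, 1.5, 300.15),
               2 * 16.043 * 1.5 / (0.082 * 300.15))
  expect_identical(ppm_to_mass(0, 1, 1.5, 300.15), 0)
  ## homogeneity in ppm
  expect_equal(ppm_to_mass(4.6, 1, 1.5, 300.15),
               2 * ppm_to_mass(2.3, 1, 1.5, 300.15))
  expect_error(ppm_to_mass(2, -1, 1.5, 300), "positive")
  expect_error(ppm_to_mass(2, 1, 1.5, 0), "positive")
  expect_error(ppm_to_mass(-1, 1, 1.5, 300), "non-negative")
})

make_series <- function(times, ppm, soil = 280, temp_K = 300.15) {
  data.frame(jar_id = "j", site = "FP1", temperature = 27,
             flooding = "wet", replicate = 1L, day = 0,
             time_s = times, ch4_ppm = ppm, pressure_atm = 1,
             volume_L = 1.5, temp_K = temp_K, soil_dry_mass_g = soil)
}

test_that("trimming drops the stabilization window and keeps 50 of 60", {
  s <- make_series(seq(10, 600, 10), rep(2, 60))
  tr <- trim_window(s)
  expect_identical(nrow(tr), 50L)
  expect_true(all(tr$time_s > 100 & tr$time_s <= 600))
  ## identity when nothing is excluded
  expect_identical(trim_window(s, exclude_first_s = 0), s)
  ## series ending before the window opens
  short <- make_series(seq(10, 90, 10), rep(2, 9))
  expect_error(trim_window(short), "insufficient")
})

test_that("flux fit recovers exact lines and matches the OLS oracle", {
  t <- seq(110, 600, 10)
  ## exact line in mass space: construct ppm from a known mass line
  a <- 3; b <- 0.004  # ug, ug/s
  ug_per_ppm <- 16.043 * 1.5 / (0.082 * 300.15)
  s <- make_series(t, (a + b * t) / ug_per_ppm)
  est <- fit_flux(s, mass_basis = "CH4")
  expect_equal(est$slope_ug_per_h, b * 3600, tolerance = 1e-12)
  expect_equal(est$flux, b * 3600 / 280, tolerance = 1e-12)
  expect_equal(est$r2, 1, tolerance = 1e-12)
  expect_equal(est$intercept, a, tolerance = 1e-9)
  ## carbon basis applies 12.011/16.043
  estC <- fit_flux(s, mass_basis = "C")
  expect_equal(estC$flux, est$flux * 12.011 / 16.043, tolerance = 1e-12)

  ## 5-point toy series against brute-force normal equations
  t5 <- c(110, 150, 260, 300, 420)
  ppm5 <- c(2.01, 2.08, 1.99, 2.31, 2.25)
  s5 <- make_series(t5, ppm5)
  est5 <- fit_flux(s5, mass_basis = "CH4")
  orc <- ols_oracle(t5, ppm_to_mass(ppm5, 1, 1.5, 300.15))
  expect_equal(est5$slope_ug_per_h, orc$slope * 3600, tolerance = 1e-12)
  expect_equal(est5$intercept, orc$intercept, tolerance = 1e-12)

  ## constant masses: zero flux, r2 defined as 0
  sc <- make_series(t, rep(2, length(t)))
  estc <- fit_flux(sc)
  expect_equal(estc$flux, 0)
  expect_identical(estc$r2, 0)

  expect_error(fit_flux(make_series(c(100, 100), c(2, 2.2))),
               "increasing")
})

test_that("flux estimator is equivariant under scaling, offset and reversal", {
  t <- seq(110, 600, 10)
  set.seed(4)
  ppm <- 2 + 0.0006 * t + rnorm(length(t), 0, 0.01)
  base <- fit_flux(make_series(t, ppm))$flux
  expect_equal(fit_flux(make_series(t, 3 * ppm))$flux, 3 * base,
               tolerance = 1e-12)
  expect_equal(fit_flux(make_series(t, ppm + 5))$flux, base,
               tolerance = 1e-9)
  ## reversing the concentration sequence in time negates the flux
  expect_equal(fit_flux(make_series(t, rev(ppm)))$flux, -base,
               tolerance = 1e-12)
})

test_that("noiseless generator output round-trips through the flux stage", {
  cfg <- experiment_config()
  for (f in c(-2e-3, -1e-4, 5e-4, 5e-3, 0.02)) {
    s <- gen_chamber_series(cfg, noiseless_truth(f))
    est <- fit_flux(trim_window(s), mass_basis = "C")
    expect_lt(abs(est$flux - f) / abs(f), 1e-9)
    expect_equal(est$r2, 1, tolerance = 1e-9)
  }
})

test_that("QC uses a strict r2 threshold and flags rather than drops", {
  est <- structure(list(r2 = 0.95, qc_pass = NA), class = "flux_estimate")
  expect_true(qc_flux(est)$qc_pass)
  est$r2 <- 0.9
  expect_false(qc_flux(est)$qc_pass)  # boundary fails
  df <- data.frame(r2 = c(0.99, 0.5))
  expect_identical(qc_flux(df)$qc_pass, c(TRUE, FALSE))
})

test_that("daily treatment means average replicates", {
  est <- data.frame(site = "FP1", temperature = 27, flooding = "wet",
                    day = 0, flux = c(0.01, 0.02, 0.03, 0.04),
                    qc_pass = TRUE)
  d <- daily_treatment_flux(est)
  expect_equal(d$mean_flux, 0.025)
  expect_identical(d$n, 4L)
  single <- daily_treatment_flux(est[2, ])
  expect_equal(single$mean_flux, 0.02)
  expect_true(is.na(single$sd_flux))
  canc <- est[1:2, ]; canc$flux <- c(-1, 1)
  expect_equal(daily_treatment_flux(canc)$mean_flux, 0)
  expect_error(daily_treatment_flux(est[0, ]), "no flux")
})

test_that("cumulative emission is the trapezoidal integral of daily means", {
  days <- c(0, 1, 3, 6, 9, 13, 17, 23, 30)
  expect_equal(cumulative_emission(days, rep(0.001, 9)), 0.72)
  expect_equal(cumulative_emission(c(0, 1), c(0, 0.01)), 0.12)
  expect_identical(cumulative_emission(days, rep(0, 9)), 0)
  expect_error(cumulative_emission(c(0, 3, 1), c(1, 2, 3)), "sorted")
  expect_error(cumulative_emission(c(0, 1, 1), c(1, 2, 3)), "sorted")
  expect_error(cumulative_emission(0, 1), "two sampling days")

  ## trapezoid is exact for the piecewise-linear interpolation it defines:
  ## compare with a fine-grid Riemann sum of approx()
  set.seed(9)
  f <- rnorm(9, 0, 0.002)
  grid <- seq(0, 30, by = 1e-3)
  fine <- approx(days, f, xout = grid)$y
  riemann <- sum((fine[-1] + fine[-length(fine)]) / 2 * diff(grid)) * 24
  expect_equal(cumulative_emission(days, f), riemann, tolerance = 1e-6)
})

test_that("the jar-level pipeline fits every jar x day and keys treatments", {
  cfg <- experiment_config(sites = "FP1", replicates = 2,
                           days = c(0, 1, 3), rng_seed = 5)
  b <- gen_experiment(cfg)
  fl <- estimate_fluxes(b$chamber)
  expect_identical(nrow(fl), nrow(b$design) * length(cfg$days))
  tr <- merge(fl, b$truth$flux, by = c("jar_id", "day"))
  expect_gt(cor(tr$flux, tr$true_flux), 0.99)
  daily <- daily_treatment_flux(fl)
  cum <- cumulative_by_treatment(daily)
  expect_identical(nrow(cum), 4L)  # 1 site x 2 temps x 2 flooding
})
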