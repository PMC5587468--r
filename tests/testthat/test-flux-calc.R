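test_that("gas-law slope conversion matches the hand-derived value and is linear", {
  expect_equal(slope_to_flux(0, 0.002, 0.01, 101325, 25), 0)
  # V/A = 0.2 m, P = 101325 Pa, T = 25 degC, dC/dt = 0.5 umol/mol/s
  f <- slope_to_flux(0.5, volume = 0.002, area = 0.01,
                     pressure = 101325, t_air = 25)
  expect_equal(f, 0.2 * 101325 / (8.314462 * 298.15) * 0.5)
  expect_equal(f, 4.087, tolerance = 1e-3)
  expect_equal(slope_to_flux(0.5, 0.002, 0.01, 101325 / 2, 25), f / 2)
  expect_equal(slope_to_flux(-0.5, 0.002, 0.01, 101325, 25), -f)
})

test_that("impossible chamber states raise errors", {
  expect_error(slope_to_flux(1, 0, 0.01, 101325, 25), "volume")
  expect_error(slope_to_flux(1, 0.002, -1, 101325, 25), "area")
  expect_error(slope_to_flux(1, 0.002, 0.01, 101325, -300), "absolute zero")
})

test_that("a noise-free linear trace is fitted exactly", {
  t <- 0:120
  co2 <- 400 + 0.3 * t
  est <- fit_flux(t, co2, volume = 0.002, area = 0.01, pressure = 101325,
                  t_air = 25, deadband_s = 25)
  expect_equal(est$flux, slope_to_flux(0.3, 0.002, 0.01, 101325, 25),
               tolerance = 1e-9)
  expect_gte(est$r2, 1 - 1e-12)
  expect_lt(est$rmse, 1e-9)
})

test_that("the exponential fit recovers the closed-form initial slope", {
  t <- 0:120
  co2 <- 1000 + (400 - 1000) * exp(-0.002 * t)
  est <- fit_flux(t, co2, volume = 0.002, area = 0.01, pressure = 101325,
                  t_air = 25, deadband_s = 0)
  expect_equal(est$model, "exponential")
  slope0 <- est$flux / slope_to_flux(1, 0.002, 0.01, 101325, 25)
  expect_equal(slope0, 0.002 * 600, tolerance = 1e-6)
})

test_that("short post-deadband windows are flagged, not fitted", {
  est <- fit_flux(0:30, 400 + 0.3 * (0:30), 0.002, 0.01, 101325, 25,
                  deadband_s = 25)
  expect_true(grepl("short_trace", est$qc_flags))
  expect_true(is.na(est$flux))
})

test_that("screening thresholds are applied per system and never delete", {
  mk <- function(flux, r2, rmse) {
    data.frame(flux = flux, r2 = r2, rmse = rmse, qc_flags = "")
  }
  kept <- qc_filter(mk(3.2, 0.99, 0.1), "automated")
  expect_true(kept$kept)
  expect_equal(kept$qc_flags, "")

  expect_equal(qc_filter(mk(17, 0.99, 0.1), "automated")$qc_flags, "range")
  a <- qc_filter(mk(3.2, 0.95, 0.1), "automated")
  expect_equal(a$qc_flags, "r2")
  expect_false(a$kept)
  m <- qc_filter(mk(3.2, 0.95, 0.1), "manual")
  expect_true(m$kept)
  expect_equal(qc_filter(mk(3.2, 0.99, 0.3), "automated")$qc_flags, "rmse")
  expect_equal(qc_filter(mk(-0.5, 0.99, 0.1), "manual")$qc_flags, "range")
  expect_equal(nrow(qc_filter(mk(c(17, 3), c(0.99, 0.99), c(0.1, 0.1)),
                              "manual")), 2)
})

test_that("screening is idempotent and monotone under threshold tightening", {
  set.seed(31)
  est <- data.frame(flux = runif(200, -2, 20), r2 = runif(200, 0.8, 1),
                    rmse = runif(200, 0, 0.4), qc_flags = "")
  once <- qc_filter(est, "manual")
  twice <- qc_filter(once, "manual")
  expect_identical(once$qc_flags, twice$qc_flags)
  expect_identical(once$kept, twice$kept)
  tight <- qc_filter(est, "manual", r2_min = 0.97)
  expect_true(all(which(tight$kept) %in% which(once$kept)))
  tight2 <- qc_filter(est, "manual", rmse_max = 0.1)
  expect_true(all(which(tight2$kept) %in% which(once$kept)))
})

test_that("the between-campaign jump rule flags only double exceedances", {
  expect_equal(campaign_jump_filter(c(4, 12, 4)), c(FALSE, TRUE, FALSE))
  expect_equal(campaign_jump_filter(c(4, 8, 4)), rep(FALSE, 3))
  expect_equal(campaign_jump_filter(rep(3, 10)), rep(FALSE, 10))
  # endpoints are never flagged even when extreme
  expect_equal(campaign_jump_filter(c(20, 4, 5, 4, 20)),
               rep(FALSE, 5))
  expect_equal(campaign_jump_filter(c(4, 12)), rep(FALSE, 2))
})
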