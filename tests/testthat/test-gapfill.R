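test_that("inverse-MSE weighting matches hand-computed two-member cases", {
  expect_equal(ensemble_weighted(cbind(2, 4), c(1, 1)), 3)
  expect_equal(ensemble_weighted(cbind(2, 4), c(1, 3)),
               (2 / 1 + 4 / 3) / (1 + 1 / 3))
  expect_equal(ensemble_weighted(cbind(2, 4), c(1, 3)), 2.5)
  # identical members: ensemble equals the common prediction whatever the MSEs
  expect_equal(ensemble_weighted(cbind(c(1, 5), c(1, 5)), c(0.2, 7)),
               c(1, 5))
})

test_that("ensemble weights are scale-invariant and the result convex", {
  set.seed(12)
  P <- matrix(rnorm(60, 3), 10, 6)
  mse <- runif(6, 0.1, 2)
  f1 <- ensemble_weighted(P, mse)
  expect_equal(f1, ensemble_weighted(P, mse * 37.5), tolerance = 1e-12)
  expect_true(all(f1 >= apply(P, 1, min) - 1e-12))
  expect_true(all(f1 <= apply(P, 1, max) + 1e-12))
})

test_that("zero member MSEs are repaired and flagged", {
  expect_warning(f <- ensemble_weighted(cbind(2, 4), c(0, 1)), "zero member")
  expect_true(is.finite(f))
  expect_lt(abs(f - 2), 0.01)    # near-perfect member dominates
})

test_that("daily and annual unit conversions match the printed constants", {
  expect_equal(daily_to_gC(1), 12e-6 * 3600 * 24)
  expect_equal(daily_to_gC(1), 1.03680)
  expect_equal(daily_to_gC(0), 0)
  # constant 1 umol m-2 s-1 for a 365-day year
  d <- data.frame(site_id = "X", day_index = 61:(61 + 364),
                  flux = 1)
  b <- integrate_annual(d)
  expect_equal(b$annual$mean_gC, 12e-6 * 3600 * 24 * 365)
  expect_equal(b$annual$mean_gC, 378.432)
})

test_that("annual integration aggregates locations with mean and standard error", {
  days <- 61:(61 + 364)
  d <- rbind(
    data.frame(site_id = "A", day_index = days, flux = 1500 / 365 / 1.0368),
    data.frame(site_id = "B", day_index = days, flux = 1700 / 365 / 1.0368)
  )
  b <- integrate_annual(d)
  expect_equal(b$annual$mean_gC, 1600, tolerance = 1e-9)
  expect_equal(b$annual$se_gC, 100, tolerance = 1e-9)
  expect_equal(b$annual$n_locations, 2)
  # partial years are excluded from the means but reported with coverage
  d2 <- rbind(d, data.frame(site_id = "C", day_index = days[1:100],
                            flux = 1))
  b2 <- integrate_annual(d2)
  expect_equal(b2$annual$n_locations, 2)
  cc <- b2$per_location[b2$per_location$site_id == "C", ]
  expect_equal(cc$coverage, 100 / 365)
})

test_that("a representable linear response is learned almost exactly", {
  cfg <- small_cfg(seed = 13)
  ed <- env_daily(generate_env(cfg))
  ft <- ed
  ft$flux <- NA_real_
  obs <- seq(1, nrow(ft), by = 5)
  ft$flux[obs] <- 1.5 + 4 * ft$swc[obs]
  m <- train_member(ft, split_seed = 2)
  expect_lt(m$mse_test, 1e-3)
})

test_that("members are deterministic per split seed and differ across seeds", {
  cfg <- small_cfg(seed = 14)
  ed <- env_daily(generate_env(cfg))
  ft <- ed
  ft$flux <- NA_real_
  obs <- seq(1, nrow(ft), by = 5)
  ft$flux[obs] <- 2 + 3 * ft$swc[obs] + 0.002 * ft$radiation[obs]
  m1 <- train_member(ft, split_seed = 5)
  m2 <- train_member(ft, split_seed = 5)
  m3 <- train_member(ft, split_seed = 6)
  expect_identical(m1$fit$wts, m2$fit$wts)
  expect_identical(m1$mse_test, m2$mse_test)
  expect_false(identical(m1$mse_test, m3$mse_test))
})

test_that("too few observed days is a clear error", {
  ft <- data.frame(day_index = 1:50, swc = runif(50), radiation = 1,
                   t_soil = 25, pressure = 101325,
                   flux = c(rnorm(10, 4), rep(NA, 40)))
  expect_error(train_member(ft), "observed days")
})

test_that("the network recovers the noise-free latent moisture response", {
  cfg <- sim_config(seed = 15, n_manual = 10L, latent_noise_cv = 0)
  env <- generate_env(cfg)
  sites <- make_collar_sites(cfg)
  lat <- generate_latent_flux(env, sites, cfg, noise = FALSE,
                              pulses = FALSE, diurnal = FALSE)
  ed <- env_daily(env)
  sid <- "M01"
  daily_true <- tapply(lat$flux[, sid], env$day_index, mean)
  ft <- ed
  ft$flux <- NA_real_
  obs <- seq(3, nrow(ft), by = 7)
  ft$flux[obs] <- daily_true[obs]
  ep <- ensemble_fill(ft, K = 5, seed = 2)
  rmse <- sqrt(mean((ep$f - daily_true)^2))
  expect_lt(rmse / mean(daily_true), 0.02)
})
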