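test_that("an exact quadratic is recovered to numerical precision", {
  swc <- seq(0.15, 0.55, length.out = 40)
  flux <- 5 - 20 * (swc - 0.45)^2
  for (rob in c(TRUE, FALSE)) {
    mr <- fit_moisture_quadratic(swc, flux, robust = rob)
    expect_equal(mr$a, 5 - 20 * 0.45^2, tolerance = 1e-10)
    expect_equal(mr$b, 2 * 20 * 0.45, tolerance = 1e-10)
    expect_equal(mr$c, -20, tolerance = 1e-10)
    expect_equal(mr$optimum, 0.45, tolerance = 1e-10)
    expect_equal(mr$r2, 1, tolerance = 1e-10)
  }
})

test_that("the bisquare fit resists a gross outlier better than least squares", {
  set.seed(21)
  swc <- runif(120, 0.15, 0.55)
  flux <- 5 - 20 * (swc - 0.45)^2 + rnorm(120, 0, 0.15)
  base <- fit_moisture_quadratic(swc, flux)$optimum
  swc_o <- c(swc, 0.2)
  flux_o <- c(flux, 16)
  rob <- fit_moisture_quadratic(swc_o, flux_o, robust = TRUE)$optimum
  ols <- fit_moisture_quadratic(swc_o, flux_o, robust = FALSE)$optimum
  expect_lt(abs(rob - base), 0.005)
  expect_gt(abs(ols - base), abs(rob - base))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_moisture_quadratic(rep(0.3, 20) + runif(20, 0, 0.01),
                                      rnorm(20)), "insufficient moisture")
  expect_error(fit_moisture_quadratic(c(0.2, 0.4), c(1, 2)), "at least 10")
})

test_that("the analytic optimum agrees with a dense-grid argmax oracle", {
  expect_equal(optimum(list(b = 18, c = -20)), 0.45)
  expect_equal(optimum(list(b = 0, c = -1)), 0)
  expect_error(optimum(list(b = 1, c = 0.5)), "convex")
  expect_error(optimum(list(b = 1, c = 0)), "zero")
  set.seed(77)
  grid <- seq(0, 1, by = 1e-3)
  for (i in 1:1000) {
    cc <- -runif(1, 1, 60)
    v <- runif(1)                  # vertex placed inside [0, 1]
    b <- -2 * cc * v
    a <- runif(1, -2, 6)
    gr <- grid[which.max(a + b * grid + cc * grid^2)]
    expect_lt(abs(optimum(list(b = b, c = cc)) - gr), 1e-3 + 1e-12)
  }
})

test_that("a record without rain contains no pulses", {
  env <- flat_env(n_days = 60, swc = 0.25)
  pl <- detect_pulses(env$time, rep(3, nrow(env)), env$swc)
  expect_equal(nrow(pl), 0)
})

test_that("ten scheduled dry-season rewetting events are all detected", {
  cfg <- ten_pulse_cfg(seed = 1)
  env <- generate_env(cfg)
  sites <- make_collar_sites(cfg)
  lat <- generate_latent_flux(env, sites, cfg)
  auto <- rowMeans(lat$flux[, sites$system == "automated"])
  pl <- detect_pulses(env$time, auto, env$swc)
  injected <- lat$truth$pulses
  dry10 <- injected[injected$dry_season, ]
  expect_gte(nrow(dry10), 10)
  matched <- vapply(dry10$time,
                    function(t0) any(abs(pl$t0 - t0) < 1), logical(1))
  expect_true(all(matched))
})

test_that("pulse counts shrink monotonically as thresholds tighten", {
  cfg <- ten_pulse_cfg(seed = 2)
  env <- generate_env(cfg)
  sites <- make_collar_sites(cfg)
  lat <- generate_latent_flux(env, sites, cfg)
  auto <- rowMeans(lat$flux[, sites$system == "automated"])
  n_at <- function(rel_min, spell) {
    nrow(detect_pulses(env$time, auto, env$swc, rel_swc_min = rel_min,
                       dry_spell_min = spell))
  }
  expect_gte(n_at(5, 5), n_at(10, 5))
  expect_gte(n_at(10, 5), n_at(20, 5))
  expect_gte(n_at(5, 5), n_at(5, 10))
  expect_gte(n_at(5, 10), n_at(5, 20))
})

test_that("pulse regression reproduces exact and degenerate relations", {
  p <- data.frame(rel_swc = c(5, 10, 20, 30), rel_flux = 5 * c(5, 10, 20, 30))
  r <- pulse_regression(p)
  expect_equal(r$slope, 5, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  flat <- data.frame(rel_swc = c(5, 10, 20), rel_flux = rep(50, 3))
  expect_equal(pulse_regression(flat)$slope, 0, tolerance = 1e-12)
  expect_error(pulse_regression(p[1:2, ]), "at least 3")
})

test_that("detected pulse magnitudes regress on moisture rises at the configured gain", {
  cfg <- ten_pulse_cfg(seed = 1)
  env <- generate_env(cfg)
  sites <- make_collar_sites(cfg)
  lat <- generate_latent_flux(env, sites, cfg)
  auto <- rowMeans(lat$flux[, sites$system == "automated"])
  pl <- detect_pulses(env$time, auto, env$swc)
  dry10 <- lat$truth$pulses[lat$truth$pulses$dry_season, ]
  keep <- vapply(seq_len(nrow(pl)),
                 function(i) any(abs(pl$t0[i] - dry10$time) < 1), logical(1))
  r <- pulse_regression(pl[keep, ])
  expect_gte(cfg$pulse_gain, r$slope_ci[1])
  expect_lte(cfg$pulse_gain, r$slope_ci[2])
})
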