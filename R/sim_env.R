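#' Generate the synthetic environmental driver series
#'
#' Produces a 30-minute environmental record with the structure the analysis
#' assumes for a seasonal tropical moist forest: soil water content with wet
#' (~0.45-0.55 cm3/cm3) and dry (declining to ~0.2) seasonal plateaus,
#' rain-event-driven upward jumps with exponential recession (e-folding
#' `swc_recession_days`), and a small dry-season diurnal drawdown; soil
#' temperature with annual and diurnal harmonics (diurnal peak 13:30);
#' shortwave radiation with a daytime arc and day-scale cloudiness; air
#' temperature, relative humidity, pressure; and per-interval rain depths from
#' a marked Poisson process whose rate and depth differ between seasons.
#'
#' Re-wetting is rain-driven: soil moisture relaxes downward toward a seasonal
#' floor but rises only through rain events (jumps into dry soil are amplified
#' to represent efficient infiltration), so a record without rain dries
#' monotonically.
#'
#' @param config a [sim_config()] object.
#' @return data.frame of class `env_series` on a strict 30-min grid with
#'   columns `time` (fractional days since start), calendar components,
#'   `hour`, `swc`, `t_soil`, `radiation`, `t_air`, `rh`, `pressure`, `rain`
#'   (mm per interval). Attribute `rain_events` records every rain event
#'   (time, depth, pre/post soil moisture) for downstream ground truth.
#' @export
generate_env <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)

  n_days <- sim_n_days(config$n_years)
  spd <- 48L                       # 30-min steps per day
  n <- n_days * spd
  dt <- 1 / spd
  time <- (seq_len(n) - 1L) * dt
  day_index <- rep(seq_len(n_days) - 1L, each = spd)
  hour <- rep((seq_len(spd) - 1L) * 0.5, n_days)
  cal <- sim_calendar(day_index, config$start_year)

  w_dry <- dry_season_weight(cal$doy)
  floor_swc <- config$swc_wet - (config$swc_wet - config$swc_dry_min) * w_dry

  ## --- rain process (marked Poisson; dry-season part optionally scheduled)
  dry_step <- is_dry_season(cal$month)
  rate <- ifelse(dry_step, config$rain_rate_dry, config$rain_rate_wet)
  depth_mean <- ifelse(dry_step, config$rain_depth_dry, config$rain_depth_wet)
  occurs <- stats::runif(n) < rate * dt
  if (!is.null(config$dry_event_days)) {
    occurs[dry_step] <- FALSE
    sched_step <- round(config$dry_event_days * spd) + 13L  # 06:30 local
    sched_step <- sched_step[sched_step >= 1 & sched_step <= n]
    occurs[sched_step] <- TRUE
    depth_mean[sched_step] <- 0  # depth assigned deterministically below
  }
  rain <- numeric(n)
  rain[occurs] <- stats::rexp(sum(occurs), rate = 1 / depth_mean[occurs])
  if (!is.null(config$dry_event_days)) {
    sched_step <- round(config$dry_event_days * spd) + 13L
    sched_step <- sched_step[sched_step >= 1 & sched_step <= n]
    rain[sched_step] <- rep_len(config$dry_event_depth_mm, length(sched_step))
  }

  ## --- soil moisture dynamics
  decay <- exp(-dt / config$swc_recession_days)
  recharge_boost <- 3
  swc <- numeric(n)
  s <- floor_swc[1] + 0.02
  for (i in seq_len(n)) {
    f <- floor_swc[i]
    if (s > f) s <- f + (s - f) * decay
    if (rain[i] > 0) {
      jump <- config$swc_per_mm * rain[i] * if (s < f) recharge_boost else 1
      s <- s + jump
    }
    if (s > 0.60) s <- 0.60
    if (s < 0.05) s <- 0.05
    swc[i] <- s
  }
  swc_base <- swc
  swc <- swc - w_dry * config$swc_diurnal_amp *
    (1 - cos(2 * pi * (hour - 8) / 24)) / 2
  swc <- pmin(0.60, pmax(0.05, swc))

  ## --- soil temperature: annual + diurnal harmonics within bounds
  diurnal_amp <- config$t_soil_diurnal_wet +
    (config$t_soil_diurnal_dry - config$t_soil_diurnal_wet) * w_dry
  t_soil <- config$t_soil_mean +
    config$t_soil_annual_amp * cos(2 * pi * (cal$doy - 91) / 365) +
    diurnal_amp * cos(2 * pi * (hour - 13.5) / 24) +
    stats::rnorm(n, 0, config$t_soil_noise_sd)

  ## --- shortwave radiation: daytime arc x day-scale cloudiness
  cloud_day <- 1 - stats::runif(n_days) * (0.45 - 0.25 * w_dry[seq(1, n, spd)])
  radiation <- (600 + 200 * w_dry) * cloud_day[day_index + 1L] *
    pmax(0, sin(pi * (hour - 6) / 12))

  ## --- air temperature, humidity, pressure
  t_air <- config$t_soil_mean + 0.2 +
    config$t_soil_annual_amp * cos(2 * pi * (cal$doy - 91) / 365) +
    (2 + 2 * w_dry) * cos(2 * pi * (hour - 14) / 24) +
    stats::rnorm(n, 0, 0.3)
  rh <- pmin(100, pmax(40, 98 - 0.03 * radiation - 8 * w_dry +
                         stats::rnorm(n, 0, 2)))
  pressure <- 101325 + 120 * cos(2 * pi * cal$doy / 365) +
    stats::rnorm(n, 0, 40)

  env <- data.frame(
    time = time, day_index = day_index, year = cal$year, month = cal$month,
    mday = cal$mday, doy = cal$doy, budget_year = cal$budget_year,
    hour = hour, swc = swc, t_soil = t_soil, radiation = radiation,
    t_air = t_air, rh = rh, pressure = pressure, rain = rain
  )
  class(env) <- c("env_series", "data.frame")

  ev <- which(rain > 0)
  attr(env, "rain_events") <- data.frame(
    step = ev,
    time = time[ev],
    day_index = day_index[ev],
    month = cal$month[ev],
    depth_mm = rain[ev],
    swc_pre = swc_base[pmax(1L, ev - 1L)],
    swc_post = swc_base[ev]
  )
  attr(env, "config") <- config
  env
}

#' Seasonal dry-season weight
#'
#' Smooth 0..1 weight that ramps up from mid December, holds 1 through the
#' core dry season, and relaxes to 0 by the end of May.
#' @param doy day of year (1..365).
#' @return numeric in \[0, 1\].
#' @keywords internal
dry_season_weight <- function(doy) {
  w <- numeric(length(doy))
  # ramp up Dec 15 (349) -> Feb 1 (wrapped length 48 days)
  p_up <- ifelse(doy >= 349, doy - 349, ifelse(doy <= 32, doy + 16, NA))
  up <- !is.na(p_up)
  w[up] <- 0.5 * (1 - cos(pi * pmin(1, p_up[up] / 48)))
  w[doy >= 33 & doy <= 105] <- 1
  down <- doy >= 106 & doy <= 151
  w[down] <- 0.5 * (1 + cos(pi * (doy[down] - 105) / 46))
  w
}

#' Aggregate the environmental series to daily resolution
#'
#' @param env an `env_series` from [generate_env()].
#' @return data.frame, one row per day: calendar components, daily mean
#'   `swc`, `t_soil`, `radiation`, `t_air`, `rh`, `pressure`, and `rain`
#'   (daily total, mm).
#' @export
env_daily <- function(env) {
  d <- env$day_index
  agg <- function(v, f = mean) as.numeric(tapply(v, d, f))
  days <- sort(unique(d))
  cal <- sim_calendar(days, attr(env, "config")$start_year %||% 2013L)
  out <- data.frame(
    day_index = days, year = cal$year, month = cal$month, mday = cal$mday,
    doy = cal$doy, budget_year = cal$budget_year,
    swc = agg(env$swc), t_soil = agg(env$t_soil),
    radiation = agg(env$radiation), t_air = agg(env$t_air),
    rh = agg(env$rh), pressure = agg(env$pressure),
    rain = agg(env$rain, sum)
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
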