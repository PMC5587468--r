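#' Synthesize raw closed-chamber concentration traces
#'
#' Turns the latent efflux field into raw chamber CO2 concentration traces
#' following the closed dynamic chamber model
#' `C(t) = C0 + (S0/k) (1 - exp(-k t))`, whose initial slope obeys the
#' ideal-gas relation `S0 = F (A/V) (R T / P)`; `k` is the chamber
#' saturation constant of the system. Additive Gaussian instrument noise is
#' applied, and a configured fraction of traces is corrupted (flattening
#' leak, transient spike, or runaway drift) to exercise quality control; a
#' ground-truth sidecar records the true flux and corruption status of every
#' trace.
#'
#' Sampling schedules follow the two systems: automated collars close for
#' 2 min sampled at 1 Hz on a 20-min cycle; manual collars close for 5 min
#' sampled every 5 s during ~weekly campaigns (collars visited sequentially
#' from 09:00).
#'
#' @param latent a `latent_flux` from [generate_latent_flux()].
#' @param config the originating [sim_config()].
#' @param system `"automated"` or `"manual"`.
#' @param days integer day indices to synthesize (default: campaign days
#'   every 7 days for manual; all days for automated -- pass a subset for
#'   tractable automated batches).
#' @param cycle_minutes automated cycle length (min).
#' @return list of class `trace_set`: `traces` (long data.frame: `trace_id`,
#'   `site_id`, `time`, `elapsed_s`, `co2`, `t_chamber`, `pressure`) and
#'   `meta` (one row per trace: geometry, `true_flux`, `corrupted`,
#'   `corrupt_type`, `timestamp`).
#' @export
synthesize_traces <- function(latent, config, system = c("manual", "automated"),
                              days = NULL, cycle_minutes = 20) {
  system <- match.arg(system)
  sites <- latent$sites[latent$sites$system == system, , drop = FALSE]
  if (!nrow(sites)) stop("no ", system, " collars in site table", call. = FALSE)
  env <- latent$env
  n_days <- max(env$day_index) + 1L

  diam_m <- (if (system == "automated") config$auto_diameter_cm
             else config$manual_diameter_cm) / 100
  area <- pi * (diam_m / 2)^2
  volume <- area * config$vol_area_ratio
  if (volume <= 0 || area <= 0) {
    stop("chamber volume and area must be positive", call. = FALSE)
  }
  k_sat <- if (system == "automated") config$k_sat_auto else config$k_sat_manual

  if (system == "automated") {
    if (is.null(days)) days <- 0:(n_days - 1L)
    tod <- seq(0, 24 - cycle_minutes / 60, by = cycle_minutes / 60) / 24
    sched <- expand.grid(site = seq_len(nrow(sites)), tod = tod, day = days)
    sched$time <- sched$day + sched$tod
    elapsed <- 0:120                       # 2 min at 1 Hz
    deadband_default <- 25
  } else {
    if (is.null(days)) days <- seq(3L, n_days - 1L, by = 7L)
    sched <- expand.grid(site = seq_len(nrow(sites)), day = days)
    sched$time <- sched$day + (9 + (sched$site - 1) * 0.125) / 24
    elapsed <- seq(0, 300, by = 5)         # 5 min at 5-s averaging
    deadband_default <- 60
  }
  sched <- sched[order(sched$time, sched$site), ]
  n_tr <- nrow(sched)

  ## interpolate state at trace start (nearest 30-min step)
  step <- pmin(nrow(env), pmax(1L, round(sched$time * 48) + 1L))
  site_col <- match(sites$site_id[sched$site], colnames(latent$flux))
  true_flux <- latent$flux[cbind(step, site_col)]
  t_chamber <- env$t_soil[step] + 0.5
  pressure <- env$pressure[step]

  set.seed(config$seed + if (system == "automated") 3L else 4L)
  c0 <- config$trace_ambient + stats::rnorm(n_tr, 0, 5)
  R <- 8.314462
  s0 <- true_flux * area * R * (t_chamber + 273.15) / (pressure * volume)

  corrupted <- stats::runif(n_tr) < config$corrupt_fraction
  corrupt_type <- rep(NA_character_, n_tr)
  corrupt_type[corrupted] <- sample(c("leak", "spike", "drift"),
                                    sum(corrupted), replace = TRUE)
  k_eff <- rep(k_sat, n_tr)
  s_eff <- s0
  k_eff[which(corrupt_type == "leak")] <- 1 / 20       # flattens within ~1 min
  dr <- which(corrupt_type == "drift")
  s_eff[dr] <- s0[dr] * stats::runif(length(dr), 5, 10)

  ## concentration matrix: traces x samples
  decay <- exp(-outer(k_eff, elapsed))                 # exp(-k t)
  cmat <- c0 + (s_eff / k_eff) * (1 - decay)
  cmat <- cmat + matrix(stats::rnorm(length(cmat), 0, config$trace_noise_sd),
                        nrow = n_tr)
  sp <- which(corrupt_type == "spike")
  for (i in sp) {
    j <- sample(5:(length(elapsed) - 5), 1)
    cmat[i, j:(j + 2)] <- cmat[i, j:(j + 2)] +
      sample(c(-1, 1), 1) * stats::runif(1, 50, 150)
  }

  trace_id <- sprintf("%s_%06d", substr(system, 1, 4), seq_len(n_tr))
  meta <- data.frame(
    trace_id = trace_id,
    site_id = sites$site_id[sched$site],
    time = sched$time,
    timestamp = sim_timestamp(sched$time, config$start_year),
    day_index = floor(sched$time),
    system = system,
    volume_m3 = volume, area_m2 = area,
    deadband_s = deadband_default,
    true_flux = true_flux,
    corrupted = corrupted, corrupt_type = corrupt_type
  )
  ns <- length(elapsed)
  traces <- data.frame(
    trace_id = rep(trace_id, each = ns),
    site_id = rep(meta$site_id, each = ns),
    time = rep(meta$time, each = ns),
    elapsed_s = rep(elapsed, times = n_tr),
    co2 = as.vector(t(cmat)),
    t_chamber = rep(t_chamber, each = ns),
    pressure = rep(pressure, each = ns)
  )
  structure(list(traces = traces, meta = meta, system = system),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set>", nrow(x$meta), x$system, "traces,",
      sum(x$meta$corrupted), "corrupted\n")
  invisible(x)
}
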