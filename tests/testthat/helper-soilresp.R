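# Shared fixtures: small configurations and constructed driver series.

small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(n_years = 1L, seed = seed, n_manual = 8L),
                            list(...))
  do.call(sim_config, args)
}

# Ten scheduled dry-season rewetting events across three dry seasons,
# mirroring a record in which ten clear pulses occur.
ten_pulse_cfg <- function(seed = 1L, ...) {
  sim_config(
    seed = seed,
    dry_event_days = c(240, 255, 270, 285, 605, 622, 640, 658, 975, 992),
    dry_event_depth_mm = c(8, 10, 12, 14, 9, 11, 13, 15, 10, 12),
    ...
  )
}

# Minimal environment table with prescribed soil moisture, for degenerate
# latent-field cases (constant drivers, no rain).
flat_env <- function(n_days = 30, swc = 0.45, start_year = 2013L) {
  spd <- 48L
  n <- n_days * spd
  time <- (seq_len(n) - 1L) / spd
  day_index <- rep(seq_len(n_days) - 1L, each = spd)
  cal <- sim_calendar(day_index, start_year)
  env <- data.frame(
    time = time, day_index = day_index, year = cal$year, month = cal$month,
    mday = cal$mday, doy = cal$doy, budget_year = cal$budget_year,
    hour = rep((seq_len(spd) - 1L) * 0.5, n_days),
    swc = swc, t_soil = 26, radiation = 0, t_air = 26, rh = 90,
    pressure = 101325, rain = 0
  )
  attr(env, "rain_events") <- data.frame()
  env
}

# Brute-force double-loop oracle for the anomaly autocorrelation.
acf_oracle <- function(f, times, breaks) {
  fbar <- colMeans(f, na.rm = TRUE)
  a <- sweep(f, 2, fbar)
  nbin <- length(breaks) - 1
  out <- rep(NA_real_, nbin)
  for (b in seq_len(nbin)) {
    num <- c()
    v1 <- c()
    v2 <- c()
    for (t1 in seq_along(times)) for (t2 in seq_along(times)) {
      if (t2 < t1) next
      lag <- times[t2] - times[t1]
      lo <- breaks[b]; hi <- breaks[b + 1]
      inb <- if (b == 1) lag >= lo & lag <= hi else lag > lo & lag <= hi
      if (!inb) next
      for (x in seq_len(nrow(f))) {
        if (is.finite(a[x, t1]) && is.finite(a[x, t2])) {
          num <- c(num, a[x, t1] * a[x, t2])
          v1 <- c(v1, a[x, t1]^2)
          v2 <- c(v2, a[x, t2]^2)
        }
      }
    }
    if (length(num)) out[b] <- mean(num) / sqrt(mean(v1) * mean(v2))
  }
  out
}

# Brute-force oracle for the semivariogram of temporal means.
semivariogram_oracle <- function(f, coords, breaks) {
  m <- rowMeans(f, na.rm = TRUE)
  nbin <- length(breaks) - 1
  g <- rep(NA_real_, nbin)
  for (b in seq_len(nbin)) {
    vals <- c()
    for (i in seq_along(m)) for (j in seq_along(m)) {
      if (j <= i) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      lo <- breaks[b]; hi <- breaks[b + 1]
      inb <- if (b == 1) r >= lo & r <= hi else r > lo & r <= hi
      if (inb) vals <- c(vals, 0.5 * (m[i] - m[j])^2)
    }
    if (length(vals)) g[b] <- mean(vals)
  }
  g
}
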