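#' Fit the quadratic soil-moisture response of soil respiration
#'
#' Fits `flux = a + b swc + c swc^2` to daily (soil moisture, efflux) pairs.
#' By default the fit is robust: iteratively reweighted least squares with a
#' Tukey bisquare loss (tuning constant 4.685, up to 50 iterations), which
#' downweights outlying days such as rewetting pulses; `robust = FALSE` gives
#' ordinary least squares. R2 and RMSE are reported against the fitted curve
#' (unweighted).
#'
#' @param swc daily volumetric soil water content (cm3/cm3).
#' @param flux daily soil CO2 efflux (umol m-2 s-1).
#' @param robust use the bisquare-weighted fit?
#' @return object of class `moisture_response`: list with `a`, `b`, `c`,
#'   `optimum` (swc at the vertex, NA when the fit is not concave), `r2`,
#'   `rmse`, `fit_domain` (swc range), `robust`, `n`.
#' @export
fit_moisture_quadratic <- function(swc, flux, robust = TRUE) {
  ok <- is.finite(swc) & is.finite(flux)
  swc <- swc[ok]; flux <- flux[ok]
  if (length(swc) < 10) {
    stop("need at least 10 (swc, flux) pairs", call. = FALSE)
  }
  if (diff(range(swc)) < 0.1) {
    stop("insufficient moisture range: swc must span at least 0.1 cm3/cm3",
         call. = FALSE)
  }
  X <- cbind(1, swc, swc^2)
  ols <- stats::lm.fit(X, flux)
  cf <- ols$coefficients
  if (robust && sqrt(mean(ols$residuals^2)) > 1e-8 * max(abs(flux), 1)) {
    rfit <- MASS::rlm(X, flux, psi = MASS::psi.bisquare, c = 4.685,
                      maxit = 50, acc = 1e-8)
    cf <- stats::coef(rfit)
  }
  pred <- drop(X %*% cf)
  res <- flux - pred
  sst <- sum((flux - mean(flux))^2)
  out <- list(
    a = unname(cf[1]), b = unname(cf[2]), c = unname(cf[3]),
    optimum = if (cf[3] < 0) unname(-cf[2] / (2 * cf[3])) else NA_real_,
    r2 = if (sst > 0) 1 - sum(res^2) / sst else 1,
    rmse = sqrt(mean(res^2)),
    fit_domain = range(swc), robust = robust, n = length(swc)
  )
  class(out) <- "moisture_response"
  out
}

#' @export
print.moisture_response <- function(x, ...) {
  cat(sprintf(
    "<moisture_response> flux = %.3f + %.3f swc %+.3f swc^2  (%s, n = %d)\n",
    x$a, x$b, x$c, if (x$robust) "robust" else "OLS", x$n))
  cat(sprintf("  optimum swc* = %.4f | R2 = %.3f | RMSE = %.3f\n",
              x$optimum, x$r2, x$rmse))
  invisible(x)
}

#' Moisture optimum of a quadratic response
#'
#' @param mr a `moisture_response`, or a list/vector with `b` and `c`.
#' @return the vertex `-b / (2c)` (cm3/cm3).
#' @export
optimum <- function(mr) {
  b <- mr[["b"]]; cc <- mr[["c"]]
  if (!is.finite(cc) || cc == 0) stop("quadratic coefficient c is zero",
                                      call. = FALSE)
  if (cc > 0) stop("response is convex (c >= 0): no interior maximum",
                   call. = FALSE)
  -b / (2 * cc)
}

#' Detect dry-season rewetting pulses of soil respiration
#'
#' Scans co-registered sub-daily efflux and soil moisture series for
#' Birch-effect pulses: within dry conditions (pre-event swc below
#' `dry_swc`), a relative soil-moisture rise of at least `rel_swc_min`
#' percent completed within 48 h, preceded by at least `dry_spell_min` days
#' without any appreciable rise (>= 2% relative, a fixed clock independent of
#' the tunable threshold so that tightening `rel_swc_min` can only shrink
#' the detection set). The pre-event flux F0 is the mean of the raw fluxes
#' over the `smooth_h` hours ending at the rise start (a backward window, so
#' the pulse itself cannot leak into the baseline) and F_max the maximum of
#' the centred rolling-mean-smoothed series within `max_window_h` hours
#' after it; smoothing keeps instrument noise from masquerading as pulse
#' magnitude.
#'
#' @param time fractional days (regular sub-daily grid).
#' @param flux efflux series (umol m-2 s-1), e.g. the spatial mean of the
#'   automated collars.
#' @param swc co-registered soil water content (cm3/cm3).
#' @param dry_swc dry-condition threshold (cm3/cm3).
#' @param rel_swc_min minimum relative swc rise (%).
#' @param dry_spell_min minimum antecedent dry spell (days).
#' @param rise_window_h window within which the rise must complete (h).
#' @param max_window_h window after the rise start searched for F_max (h).
#' @param smooth_h rolling-mean width applied to `flux` (h; 0 disables).
#' @param rise_eps minimum single-step swc increment (cm3/cm3) that starts a
#'   candidate rise; keeps the slow nightly recovery of the diurnal drawdown
#'   from being mistaken for a rain signal.
#' @return data.frame of pulse events: `t0`, `t_max`, `F0`, `F_max`, `swc0`,
#'   `swc_max`, `rel_flux` and `rel_swc` (both %).
#' @export
detect_pulses <- function(time, flux, swc, dry_swc = 0.35, rel_swc_min = 5,
                          dry_spell_min = 5, rise_window_h = 48,
                          max_window_h = 72, smooth_h = 6, rise_eps = 5e-4) {
  n <- length(time)
  stopifnot(length(flux) == n, length(swc) == n, n > 2)
  dt <- stats::median(diff(time))
  fs <- flux
  if (smooth_h > 0) {
    w <- max(1L, round(smooth_h / 24 / dt))
    if (w %% 2 == 0) w <- w + 1L
    fs <- stats::filter(flux, rep(1 / w, w), sides = 2)
    fs <- as.numeric(fs)
    fs[is.na(fs)] <- flux[is.na(fs)]
  }

  ## candidate rises: group consecutive positive swc increments
  inc <- c(0, diff(swc))
  rising <- inc > rise_eps
  starts <- which(rising & !c(FALSE, rising[-n]))
  events <- list()
  last_rise <- -Inf
  for (s in starts) {
    i0 <- s - 1L
    if (i0 < 1L) next
    swc0 <- swc[i0]
    horizon <- which(time > time[i0] & time <= time[i0] + rise_window_h / 24)
    if (!length(horizon)) next
    swc_max <- max(swc[horizon])
    rel_swc <- 100 * (swc_max - swc0) / swc0
    if (rel_swc >= 2) {
      spell <- time[i0] - last_rise
      last_rise <- time[i0]
    } else {
      next
    }
    if (swc0 >= dry_swc || rel_swc < rel_swc_min || spell < dry_spell_min) next
    back <- which(time <= time[i0] & time > time[i0] - max(smooth_h, 1) / 24)
    f0 <- mean(flux[back], na.rm = TRUE)
    if (!is.finite(f0) || f0 <= 0) next
    mwin <- which(time > time[i0] & time <= time[i0] + max_window_h / 24)
    if (!length(mwin)) next
    imax <- mwin[which.max(fs[mwin])]
    events[[length(events) + 1L]] <- data.frame(
      t0 = time[i0], t_max = time[imax],
      F0 = f0, F_max = fs[imax],
      swc0 = swc0, swc_max = swc_max,
      rel_flux = 100 * (fs[imax] - f0) / f0,
      rel_swc = rel_swc
    )
  }
  if (!length(events)) {
    return(data.frame(t0 = numeric(), t_max = numeric(), F0 = numeric(),
                      F_max = numeric(), swc0 = numeric(),
                      swc_max = numeric(), rel_flux = numeric(),
                      rel_swc = numeric()))
  }
  do.call(rbind, events)
}

#' Regress pulse magnitude on soil-moisture rise
#'
#' Ordinary least squares of the relative flux increase on the relative soil
#' moisture increase across detected pulses.
#'
#' @param pulses data.frame from [detect_pulses()] (needs `rel_flux`,
#'   `rel_swc`).
#' @return list: `slope`, `intercept`, `r2`, `p` (slope t-test), `n`, and
#'   `slope_ci` (95% confidence interval).
#' @export
pulse_regression <- function(pulses) {
  if (nrow(pulses) < 3) stop("need at least 3 pulses", call. = FALSE)
  fit <- stats::lm(rel_flux ~ rel_swc, data = pulses)
  sm <- summary(fit)
  slope_row <- sm$coefficients["rel_swc", ]
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p = unname(slope_row["Pr(>|t|)"]),
    n = nrow(pulses),
    slope_ci = unname(stats::confint(fit)["rel_swc", ])
  )
}
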