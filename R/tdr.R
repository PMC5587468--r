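#' Convert gravimetric to volumetric soil water content
#'
#' `swc = theta_g x rho_b / rho_w` with the density of water
#' `rho_w = 1 g/cm3`.
#'
#' @param theta_g gravimetric water content (g water / g dry soil).
#' @param rho_b soil bulk density (g/cm3; site default 0.75).
#' @return volumetric water content (cm3/cm3).
#' @export
gravimetric_to_volumetric <- function(theta_g, rho_b = 0.75) {
  if (any(rho_b <= 0)) stop("bulk density must be positive", call. = FALSE)
  if (any(theta_g < 0, na.rm = TRUE)) {
    stop("gravimetric water content cannot be negative", call. = FALSE)
  }
  theta_g * rho_b / 1
}

#' Calibrate a TDR sensor against gravimetric samples
#'
#' Maps the raw TDR period reading to volumetric soil water content via a
#' quadratic least-squares fit of the gravimetric samples (converted with
#' the site bulk density). The fitted mapping must be monotone increasing
#' over the calibrated period range; predictions outside that range are
#' flagged as extrapolation.
#'
#' @param period sensor period readings of the calibration samples.
#' @param theta_g paired gravimetric water contents (g/g).
#' @param rho_b site bulk density (g/cm3).
#' @return object of class `tdr_calibration`: coefficients, `r2`, `rmse`,
#'   `range` (calibrated period range), and `rho_b`. Use
#'   [predict.tdr_calibration()] to apply it.
#' @export
fit_tdr_calibration <- function(period, theta_g, rho_b = 0.75) {
  ok <- is.finite(period) & is.finite(theta_g)
  period <- period[ok]; theta_g <- theta_g[ok]
  if (length(period) < 4) {
    stop("need at least 4 calibration samples", call. = FALSE)
  }
  swc <- gravimetric_to_volumetric(theta_g, rho_b)
  fit <- stats::lm(swc ~ period + I(period^2))
  cf <- stats::coef(fit)
  rng <- range(period)
  # derivative b + 2c p must stay positive over the calibrated range
  deriv <- cf[2] + 2 * cf[3] * rng
  if (any(deriv <= 0)) {
    stop("fitted period->swc mapping is not monotone increasing over the ",
         "calibrated range", call. = FALSE)
  }
  res <- stats::residuals(fit)
  sst <- sum((swc - mean(swc))^2)
  structure(list(coefficients = cf,
                 r2 = if (sst > 0) 1 - sum(res^2) / sst else 1,
                 rmse = sqrt(mean(res^2)),
                 range = rng, rho_b = rho_b, n = length(period)),
            class = "tdr_calibration")
}

#' Apply a TDR calibration
#'
#' @param object a `tdr_calibration`.
#' @param period new period readings.
#' @param ... unused.
#' @return data.frame: `period`, `swc`, `extrapolated`.
#' @export
predict.tdr_calibration <- function(object, period, ...) {
  cf <- object$coefficients
  data.frame(period = period,
             swc = cf[1] + cf[2] * period + cf[3] * period^2,
             extrapolated = period < object$range[1] |
               period > object$range[2])
}

#' @export
print.tdr_calibration <- function(x, ...) {
  cat(sprintf(
    "<tdr_calibration> swc = %.4g %+.4g p %+.4g p^2 | R2 %.3f | n %d\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3], x$r2, x$n))
  invisible(x)
}
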