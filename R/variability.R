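#' Build a collar x campaign flux matrix
#'
#' Arranges kept flux estimates as f(x, t): one row per collar, one column
#' per campaign (or day). Multiple kept values of a collar within a campaign
#' are averaged; missing entries are NA.
#'
#' @param estimates data.frame with `site_id`, `flux`, and either a campaign
#'   grouping column `campaign` or `day_index` (used as campaign id).
#' @param sites optional `collar_sites` table supplying coordinates.
#' @param times optional numeric time of each campaign (defaults to the
#'   campaign ids, which for `day_index` are days).
#' @return list of class `flux_matrix`: `f` (matrix sites x times), `times`,
#'   `site_id`, `coords` (matrix or NULL).
#' @export
flux_matrix <- function(estimates, sites = NULL, times = NULL) {
  camp <- if ("campaign" %in% names(estimates)) estimates$campaign
  else estimates$day_index
  if (is.null(camp)) stop("estimates need a campaign or day_index column",
                          call. = FALSE)
  if ("kept" %in% names(estimates)) estimates <- estimates[estimates$kept, ]
  camp <- if ("campaign" %in% names(estimates)) estimates$campaign
  else estimates$day_index
  ids <- sort(unique(estimates$site_id))
  cols <- sort(unique(camp))
  f <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  agg <- tapply(estimates$flux, list(estimates$site_id, camp), mean)
  f[rownames(agg), colnames(agg)] <- agg
  coords <- NULL
  if (!is.null(sites)) {
    m <- match(ids, sites$site_id)
    coords <- cbind(x = sites$x[m], y = sites$y[m])
    rownames(coords) <- ids
  }
  structure(list(f = f, times = if (is.null(times)) as.numeric(cols)
                 else times,
                 site_id = ids, coords = coords),
            class = "flux_matrix")
}

#' Temporal autocorrelation of flux anomalies
#'
#' Autocorrelation of f(x, t) after removing the spatial mean of each
#' campaign:
#' `acf(tau) = E[(f(x,t) - fbar_t)(f(x,t+tau) - fbar_{t+tau})] /
#'  sqrt(E[(f(x,t) - fbar_t)^2] E[(f(x,t+tau) - fbar_{t+tau})^2])`,
#' the expectation running over all collars and ordered campaign pairs whose
#' spacing falls in a lag bin. Campaigns need not be equally spaced; the
#' default bin width is the median campaign spacing.
#'
#' @param M a `flux_matrix`.
#' @param lag_breaks numeric break points of the lag bins (same units as
#'   `M$times`); default covers 0 to the record span at the median spacing.
#' @return data.frame: `lag` (bin midpoint), `acf`, `n` (pairs), `reliable`
#'   (n >= 5). The zero-lag bin equals 1 by construction.
#' @export
temporal_acf <- function(M, lag_breaks = NULL) {
  f <- M$f; times <- M$times
  a <- sweep(f, 2, colMeans(f, na.rm = TRUE))   # anomalies
  if (is.null(lag_breaks)) {
    bw <- stats::median(diff(sort(times)))
    lag_breaks <- seq(-bw / 2, diff(range(times)) + bw / 2, by = bw)
  }
  nt <- length(times)
  pairs <- expand.grid(i = seq_len(nt), j = seq_len(nt))
  pairs <- pairs[pairs$j >= pairs$i, ]
  lag <- times[pairs$j] - times[pairs$i]
  bin <- cut(lag, lag_breaks, include.lowest = TRUE, labels = FALSE)
  res <- lapply(sort(unique(bin[!is.na(bin)])), function(b) {
    sel <- which(bin == b)
    a1 <- as.vector(a[, pairs$i[sel], drop = FALSE])
    a2 <- as.vector(a[, pairs$j[sel], drop = FALSE])
    ok <- is.finite(a1) & is.finite(a2)
    a1 <- a1[ok]; a2 <- a2[ok]
    denom <- sqrt(mean(a1^2) * mean(a2^2))
    data.frame(
      lag = (lag_breaks[b] + lag_breaks[b + 1]) / 2,
      acf = if (length(a1) && denom > 0) mean(a1 * a2) / denom else NA_real_,
      n = length(a1)
    )
  })
  out <- do.call(rbind, res)
  out$reliable <- out$n >= 5
  out
}

#' Semivariogram of temporally averaged fluxes
#'
#' `gamma(r) = E[ (1/2) (fbar(x) - fbar(x+r))^2 ]` where `fbar(x)` is the
#' temporal mean at collar x; the expectation runs over all unordered collar
#' pairs whose separation falls in a distance bin. A flat semivariogram
#' (pure nugget) indicates no spatial structure at the sampled scales.
#'
#' @param M a `flux_matrix` with coordinates.
#' @param distance_breaks bin breaks (m); default 10-m bins from 0 to the
#'   maximum separation.
#' @param stratum optional logical over campaigns selecting e.g. wet or dry
#'   campaigns before temporal averaging.
#' @return data.frame: `distance` (bin midpoint), `gamma`, `n` (pairs),
#'   `empty`.
#' @export
semivariogram <- function(M, distance_breaks = NULL, stratum = NULL) {
  if (is.null(M$coords)) stop("flux_matrix carries no coordinates",
                              call. = FALSE)
  f <- M$f
  if (!is.null(stratum)) f <- f[, stratum, drop = FALSE]
  m <- rowMeans(f, na.rm = TRUE)
  d <- as.matrix(stats::dist(M$coords))
  if (is.null(distance_breaks)) {
    distance_breaks <- seq(0, max(d) + 10, by = 10)
  }
  ns <- length(m)
  pr <- which(upper.tri(d), arr.ind = TRUE)
  sep <- d[pr]
  half_sq <- 0.5 * (m[pr[, 1]] - m[pr[, 2]])^2
  bin <- cut(sep, distance_breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    distance = (distance_breaks[-length(distance_breaks)] +
                  distance_breaks[-1]) / 2,
    gamma = NA_real_, n = 0L
  )
  for (b in sort(unique(bin[!is.na(bin)]))) {
    sel <- which(bin == b & is.finite(half_sq))
    out$gamma[b] <- mean(half_sq[sel])
    out$n[b] <- length(sel)
  }
  out$empty <- out$n == 0
  out
}

#' Coefficients of variation in time and space
#'
#' Temporal CV (sd/mean over campaigns) per collar and spatial CV (sd/mean
#' over collars of the temporal means), using sample (n-1) standard
#' deviations. Collars with fewer than `min_obs` observations in the stratum
#' get NA.
#'
#' @param M a `flux_matrix`.
#' @param stratum optional logical over campaigns (e.g. wet/dry split).
#' @param min_obs minimum observations per collar.
#' @return list: `temporal_cv` (named per collar), `spatial_cv`,
#'   `temporal_mean` (named per collar).
#' @export
cv_stats <- function(M, stratum = NULL, min_obs = 3) {
  f <- M$f
  if (!is.null(stratum)) f <- f[, stratum, drop = FALSE]
  nobs <- rowSums(is.finite(f))
  mu <- rowMeans(f, na.rm = TRUE)
  sdv <- apply(f, 1, stats::sd, na.rm = TRUE)
  tcv <- ifelse(nobs >= min_obs & mu != 0, sdv / mu, NA_real_)
  ok <- is.finite(mu)
  list(
    temporal_cv = setNames(tcv, M$site_id),
    spatial_cv = stats::sd(mu[ok]) / mean(mu[ok]),
    temporal_mean = setNames(mu, M$site_id)
  )
}

#' Rescale a series to the unit interval
#'
#' @param x numeric vector.
#' @return `(x - min) / (max - min)`; error on zero range.
#' @export
normalize01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) <= 0) stop("zero-range series cannot be normalized",
                         call. = FALSE)
  (x - r[1]) / diff(r)
}

#' Composite diurnal cycle
#'
#' Averages a sub-daily series into time-of-day bins (mean per bin), e.g.
#' continuous dry-season measurements, and reports the peak-to-trough
#' amplitude, peak time, and the 0-1 normalized shape used to compare
#' variables with different units.
#'
#' @param time fractional days.
#' @param value series to composite.
#' @param mask optional logical selecting the season/subset.
#' @param bin_minutes bin width (min).
#' @param min_days minimum distinct days contributing per bin (bins below
#'   are NA).
#' @return object of class `diurnal_composite`: data.frame-like list with
#'   `hour` (bin midpoints), `mean`, `n`, `normalized`, plus `amplitude`
#'   (native units) and `peak_hour`.
#' @export
composite_diurnal <- function(time, value, mask = NULL, bin_minutes = 30,
                              min_days = 5) {
  if (!is.null(mask)) {
    time <- time[mask]; value <- value[mask]
  }
  tod <- (time %% 1) * 24
  nb <- round(24 * 60 / bin_minutes)
  bin <- floor(tod / 24 * nb + 1e-9) %% nb + 1L
  day <- floor(time)
  mean_b <- rep(NA_real_, nb)
  n_b <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- bin == b & is.finite(value)
    n_days_b <- length(unique(day[sel]))
    n_b[b] <- sum(sel)
    if (n_days_b >= min_days) mean_b[b] <- mean(value[sel])
  }
  hour <- (seq_len(nb) - 0.5) * 24 / nb
  amp <- diff(range(mean_b, na.rm = TRUE))
  out <- list(hour = hour, mean = mean_b, n = n_b,
              normalized = tryCatch(normalize01(mean_b),
                                    error = function(e) rep(NA_real_, nb)),
              amplitude = amp,
              peak_hour = hour[which.max(mean_b)],
              bin_minutes = bin_minutes)
  class(out) <- "diurnal_composite"
  out
}

#' @export
print.diurnal_composite <- function(x, ...) {
  cat(sprintf(
    "<diurnal_composite> %d-min bins | amplitude %.3f | peak %.1f h\n",
    x$bin_minutes, x$amplitude, x$peak_hour))
  invisible(x)
}

#' Phase lag between two diurnal composites
#'
#' Circular cross-correlation maximizer over 24 h: the lag (in hours, in
#' (-12, 12]) by which the second composite trails the first. Both
#' composites must share the bin grid.
#'
#' @param c1,c2 `diurnal_composite` objects (or numeric vectors on the same
#'   time-of-day grid).
#' @return lag in hours; positive when `c2` peaks after `c1`.
#' @export
phase_lag <- function(c1, c2) {
  v1 <- if (inherits(c1, "diurnal_composite")) c1$mean else c1
  v2 <- if (inherits(c2, "diurnal_composite")) c2$mean else c2
  if (length(v1) != length(v2)) stop("composites are on different bin grids",
                                     call. = FALSE)
  nb <- length(v1)
  v1 <- v1 - mean(v1, na.rm = TRUE)
  v2 <- v2 - mean(v2, na.rm = TRUE)
  v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
  cc <- vapply(0:(nb - 1), function(s) {
    sum(v1 * v2[((seq_len(nb) - 1 + s) %% nb) + 1])
  }, numeric(1))
  lag <- (which.max(cc) - 1) * 24 / nb
  if (lag > 12) lag <- lag - 24
  lag
}
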