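#' Convert a concentration slope to a soil CO2 efflux
#'
#' Standard closed-chamber ideal-gas conversion:
#' `F = P V / (R (T + 273.15) A) * dCdt` with R = 8.314462 J mol-1 K-1.
#'
#' @param dCdt concentration slope (umol mol-1 s-1).
#' @param volume chamber system volume V (m3).
#' @param area collar area A (m2).
#' @param pressure air pressure (Pa).
#' @param t_air chamber air temperature (degC).
#' @return efflux (umol m-2 s-1); linear in `dCdt`, same sign.
#' @examples
#' slope_to_flux(0.5, volume = 0.002, area = 0.01,
#'               pressure = 101325, t_air = 25)  # ~4.087
#' @export
slope_to_flux <- function(dCdt, volume, area, pressure, t_air) {
  if (any(volume <= 0)) stop("chamber volume must be positive", call. = FALSE)
  if (any(area <= 0)) stop("collar area must be positive", call. = FALSE)
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  if (any(t_air <= -273.15)) {
    stop("temperature below absolute zero", call. = FALSE)
  }
  pressure * volume / (8.314462 * (t_air + 273.15) * area) * dCdt
}

#' Fit one chamber trace and estimate its efflux
#'
#' Regresses CO2 concentration against time on the post-deadband window.
#' The linear model is ordinary least squares; the exponential chamber model
#' `C(t) = C0 + (S0/a)(1 - exp(-a (t - t0)))` (C0 fixed at the first
#' post-deadband observation; S0 the initial slope, a the saturation rate) is
#' fitted by nonlinear least squares. Under the automated policy both models
#' are fitted and the one with higher R2 selected (ties go to linear); the
#' manual policy is linear only. The slope at the window start is converted
#' through [slope_to_flux()]. The residual RMSE (concentration units) is
#' expressed in flux-equivalent units by dividing by the window duration and
#' applying the same gas-law conversion, which makes the 0.2 umol m-2 s-1
#' screening threshold applicable.
#'
#' @param elapsed_s,co2 trace samples (s; umol mol-1), elapsed strictly
#'   increasing.
#' @param volume,area,pressure,t_air chamber geometry and air state.
#' @param deadband_s seconds discarded at the start (25 automated,
#'   60 manual).
#' @param model_policy `"best"` (automated: best of linear/exponential by R2)
#'   or `"linear"` (manual).
#' @param end_s optional end of the fit window (s).
#' @return one-row data.frame: `flux`, `model`, `r2`, `rmse` (flux units),
#'   `window_s`, `qc_flags` (informational flags from fitting, `;`-joined).
#' @export
fit_flux <- function(elapsed_s, co2, volume, area, pressure, t_air,
                     deadband_s = 25, model_policy = c("best", "linear"),
                     end_s = NULL) {
  model_policy <- match.arg(model_policy)
  keep <- elapsed_s >= deadband_s
  if (!is.null(end_s)) keep <- keep & elapsed_s <= end_s
  t <- elapsed_s[keep]
  y <- co2[keep]
  flags <- character(0)
  if (length(t) < 10) {
    return(data.frame(flux = NA_real_, model = NA_character_, r2 = NA_real_,
                      rmse = NA_real_, window_s = diff(range(t, 0)),
                      qc_flags = "short_trace"))
  }
  dur <- max(t) - min(t)
  sst <- sum((y - mean(y))^2)
  r2_of <- function(res) if (sst > 0) 1 - sum(res^2) / sst else 1

  ## linear OLS
  tc <- t - mean(t)
  slope_lin <- sum(tc * (y - mean(y))) / sum(tc^2)
  res_lin <- y - (mean(y) + slope_lin * tc)
  r2_lin <- r2_of(res_lin)
  rmse_lin <- sqrt(mean(res_lin^2))

  slope <- slope_lin; model <- "linear"; res <- res_lin; r2 <- r2_lin
  rmse_c <- rmse_lin
  if (model_policy == "best") {
    t0 <- min(t)
    c0 <- y[which.min(t)]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c0 + s0 / a * (1 - exp(-a * (t - t0))),
        start = list(s0 = slope_lin, a = 1e-3),
        lower = c(s0 = -Inf, a = 1e-8), upper = c(s0 = Inf, a = 1),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) {
      flags <- c(flags, "exp_failed")
    } else {
      res_exp <- stats::residuals(fit)
      r2_exp <- r2_of(res_exp)
      if (r2_exp > r2_lin) {           # ties go to linear
        slope <- stats::coef(fit)[["s0"]]
        model <- "exponential"; res <- res_exp; r2 <- r2_exp
        rmse_c <- sqrt(mean(res_exp^2))
      }
    }
  }
  flux <- slope_to_flux(slope, volume, area, pressure, t_air)
  rmse_flux <- slope_to_flux(rmse_c / dur, volume, area, pressure, t_air)
  data.frame(flux = flux, model = model, r2 = r2, rmse = rmse_flux,
             window_s = dur,
             qc_flags = paste(flags, collapse = ";"))
}

#' Fit every trace of a trace set
#'
#' @param trace_set a `trace_set` from [synthesize_traces()], or a list with
#'   `traces` (long data.frame) and `meta`.
#' @param deadband_s deadband override (default: per-system values carried in
#'   `meta`).
#' @param model_policy override; default `"best"` for automated traces,
#'   `"linear"` for manual.
#' @return data.frame of flux estimates, one row per trace (`trace_id`,
#'   `site_id`, `time`, `day_index`, `system`, `flux`, `model`, `r2`, `rmse`,
#'   `window_s`, `qc_flags`, plus `true_flux`/`corrupted` when present in the
#'   sidecar).
#' @export
fit_fluxes <- function(trace_set, deadband_s = NULL, model_policy = NULL) {
  meta <- trace_set$meta
  tr <- trace_set$traces
  if (is.null(model_policy)) {
    model_policy <- if (identical(trace_set$system, "automated")) "best"
    else "linear"
  }
  idx <- split(seq_len(nrow(tr)), tr$trace_id)
  idx <- idx[meta$trace_id]
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    j <- idx[[i]]
    db <- if (is.null(deadband_s)) meta$deadband_s[i] else deadband_s
    out[[i]] <- fit_flux(tr$elapsed_s[j], tr$co2[j],
                         volume = meta$volume_m3[i], area = meta$area_m2[i],
                         pressure = tr$pressure[j][1],
                         t_air = tr$t_chamber[j][1],
                         deadband_s = db, model_policy = model_policy)
  }
  est <- do.call(rbind, out)
  cols <- intersect(c("trace_id", "site_id", "time", "day_index", "system",
                      "true_flux", "corrupted"), names(meta))
  cbind(meta[, cols, drop = FALSE], est)
}

#' Quality-control screening of flux estimates
#'
#' Flags (never deletes) estimates violating the screening thresholds: flux
#' outside the plausible 0--16 umol m-2 s-1 window (`range`), coefficient of
#' determination below the system threshold -- 0.97 automated, 0.9 manual --
#' (`r2`), or flux-equivalent RMSE above 0.2 umol m-2 s-1 (`rmse`). `kept` is
#' TRUE iff no disqualifying flag is present (informational fit flags such as
#' `exp_failed` do not disqualify). Screening is idempotent and
#' order-independent.
#'
#' @param estimates data.frame from [fit_fluxes()] (needs `flux`, `r2`,
#'   `rmse`, `qc_flags`).
#' @param system `"automated"` or `"manual"`.
#' @param flux_range plausible flux limits (umol m-2 s-1).
#' @param r2_min override for the R2 threshold.
#' @param rmse_max RMSE threshold (umol m-2 s-1).
#' @return `estimates` with updated `qc_flags` and a logical `kept` column.
#' @export
qc_filter <- function(estimates, system = c("automated", "manual"),
                      flux_range = c(0, 16), r2_min = NULL, rmse_max = 0.2) {
  system <- match.arg(system)
  if (is.null(r2_min)) r2_min <- if (system == "automated") 0.97 else 0.9
  disq <- c("range", "r2", "rmse", "jump", "short_trace")
  base <- strsplit(ifelse(is.na(estimates$qc_flags), "", estimates$qc_flags),
                   ";", fixed = TRUE)
  new_flags <- vapply(seq_len(nrow(estimates)), function(i) {
    fl <- setdiff(base[[i]], c("range", "r2", "rmse", ""))
    f <- estimates$flux[i]
    if (is.na(f)) {
      if (!"short_trace" %in% fl) fl <- c(fl, "short_trace")
    } else {
      if (f < flux_range[1] || f > flux_range[2]) fl <- c(fl, "range")
      if (estimates$r2[i] < r2_min) fl <- c(fl, "r2")
      if (estimates$rmse[i] > rmse_max) fl <- c(fl, "rmse")
    }
    paste(fl, collapse = ";")
  }, character(1))
  estimates$qc_flags <- new_flags
  estimates$kept <- !vapply(strsplit(new_flags, ";", fixed = TRUE),
                            function(f) any(f %in% disq), logical(1))
  estimates
}

#' Flag between-campaign jumps in a collar's series
#'
#' An interior campaign value is anomalous iff it differs from **both** its
#' previous and following values by more than `max_jump`; endpoints are never
#' flagged. Values are compared in time order; gaps between campaigns do not
#' reset the rule.
#'
#' @param flux ordered campaign fluxes of one collar (umol m-2 s-1).
#' @param max_jump threshold (default 5 umol m-2 s-1).
#' @return logical vector, TRUE where flagged.
#' @export
campaign_jump_filter <- function(flux, max_jump = 5) {
  n <- length(flux)
  flag <- rep(FALSE, n)
  if (n < 3) return(flag)
  i <- 2:(n - 1)
  flag[i] <- abs(flux[i] - flux[i - 1]) > max_jump &
    abs(flux[i] - flux[i + 1]) > max_jump
  flag & !is.na(flag)
}

#' Apply the jump rule across a campaign flux table
#'
#' Adds a `jump` flag per collar (on kept values, in time order) and updates
#' `kept`.
#'
#' @param estimates QC'd estimates from [qc_filter()] with `site_id`, `time`.
#' @param max_jump threshold (umol m-2 s-1).
#' @return `estimates` with `jump` flags merged into `qc_flags` and `kept`
#'   updated.
#' @export
apply_jump_filter <- function(estimates, max_jump = 5) {
  for (sid in unique(estimates$site_id)) {
    rows <- which(estimates$site_id == sid & estimates$kept)
    rows <- rows[order(estimates$time[rows])]
    if (length(rows) < 3) next
    fl <- campaign_jump_filter(estimates$flux[rows], max_jump)
    hit <- rows[fl]
    if (length(hit)) {
      estimates$qc_flags[hit] <- ifelse(nzchar(estimates$qc_flags[hit]),
                                        paste0(estimates$qc_flags[hit],
                                               ";jump"), "jump")
      estimates$kept[hit] <- FALSE
    }
  }
  estimates
}
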