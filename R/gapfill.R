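#' Daily feature table for gap-filling
#'
#' Joins the gap-free daily meteorological drivers (soil moisture, solar
#' radiation, soil temperature, pressure) with the sparse observed daily
#' efflux of one location.
#'
#' @param env_d daily environment table from [env_daily()].
#' @param estimates kept flux estimates of one location (needs `day_index`,
#'   `flux`; multiple values per day are averaged).
#' @param drivers driver column names used as ANN inputs.
#' @return data.frame: `day_index`, drivers, `flux` (NA on unobserved days).
#' @export
feature_table <- function(env_d, estimates,
                          drivers = c("swc", "radiation", "t_soil",
                                      "pressure")) {
  stopifnot(all(drivers %in% names(env_d)))
  ft <- env_d[, c("day_index", "budget_year", "month", drivers)]
  obs <- tapply(estimates$flux, estimates$day_index, mean)
  ft$flux <- as.numeric(obs[as.character(ft$day_index)])
  ft
}

#' Train one neural-network ensemble member
#'
#' Splits the observed days of a location randomly into training (70%),
#' validation (15%) and test (15%) sets, standardises the inputs with
#' training-set statistics, and trains a feed-forward network with one
#' hidden layer of `hidden` sigmoid units and a linear output. Training
#' proceeds in optimisation chunks and stops when the validation MSE has not
#' improved for `patience` consecutive checks (early stopping); the weights
#' with the best validation MSE are kept and the held-out test MSE reported.
#'
#' @param features a [feature_table()].
#' @param split_seed integer seed controlling the split and the initial
#'   weights; same seed, same member.
#' @param hidden hidden units.
#' @param patience validation checks without improvement before stopping.
#' @param chunk_iters optimiser iterations between validation checks.
#' @param max_chunks cap on chunks.
#' @param decay weight decay of the optimiser.
#' @param min_obs minimum observed days required.
#' @param drivers input columns.
#' @return list of class `ann_member`: `fit` (nnet object with best
#'   weights), `center`, `scale`, `drivers`, `mse_val`, `mse_test`,
#'   `split_seed`.
#' @export
train_member <- function(features, split_seed = 1L, hidden = 10L,
                         patience = 6L, chunk_iters = 30L, max_chunks = 40L,
                         decay = 1e-4, min_obs = 40L,
                         drivers = c("swc", "radiation", "t_soil",
                                     "pressure")) {
  obs <- features[is.finite(features$flux), , drop = FALSE]
  if (nrow(obs) < min_obs) {
    stop(sprintf("only %d observed days (need >= %d)", nrow(obs), min_obs),
         call. = FALSE)
  }
  set.seed(split_seed)
  n <- nrow(obs)
  idx <- sample.int(n)
  n_tr <- floor(0.70 * n)
  n_va <- floor(0.15 * n)
  i_tr <- idx[seq_len(n_tr)]
  i_va <- idx[n_tr + seq_len(n_va)]
  i_te <- idx[(n_tr + n_va + 1):n]

  X <- as.matrix(obs[, drivers, drop = FALSE])
  y <- obs$flux
  ctr <- colMeans(X[i_tr, , drop = FALSE])
  scl <- apply(X[i_tr, , drop = FALSE], 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  fit <- nnet::nnet(Xs[i_tr, , drop = FALSE], y[i_tr], size = hidden,
                    linout = TRUE, decay = decay, maxit = chunk_iters,
                    trace = FALSE)
  mse <- function(w_fit, rows) {
    mean((y[rows] - stats::predict(w_fit, Xs[rows, , drop = FALSE]))^2)
  }
  best_val <- mse(fit, i_va)
  best_wts <- fit$wts
  stale <- 0L
  for (ch in seq_len(max_chunks - 1L)) {
    fit <- nnet::nnet(Xs[i_tr, , drop = FALSE], y[i_tr], size = hidden,
                      linout = TRUE, decay = decay, maxit = chunk_iters,
                      Wts = fit$wts, trace = FALSE)
    v <- mse(fit, i_va)
    if (v < best_val - 1e-10) {
      best_val <- v; best_wts <- fit$wts; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  fit$wts <- best_wts
  structure(list(fit = fit, center = ctr, scale = scl, drivers = drivers,
                 mse_val = best_val, mse_test = mse(fit, i_te),
                 split_seed = split_seed),
            class = "ann_member")
}

#' Predict a member on all days
#'
#' @param member an `ann_member`.
#' @param features a [feature_table()].
#' @return numeric predictions for every row of `features`.
#' @export
predict_member <- function(member, features) {
  X <- as.matrix(features[, member$drivers, drop = FALSE])
  Xs <- sweep(sweep(X, 2, member$center), 2, member$scale, "/")
  as.numeric(stats::predict(member$fit, Xs))
}

#' Inverse-MSE weighted ensemble combination
#'
#' `f_j = sum_k (f_jk / MSE_k) / sum_k (1 / MSE_k)`: members with smaller
#' held-out test error get proportionally larger weight. A zero MSE is
#' replaced by the smallest positive member MSE times 1e-3 (flagged via a
#' warning) so weights stay finite. The result is a convex combination, so
#' it lies within the member envelope and is invariant to rescaling all MSEs
#' by a common factor.
#'
#' @param predictions matrix (days x members).
#' @param mse member test MSEs (length = ncol).
#' @return numeric ensemble prediction per day.
#' @export
ensemble_weighted <- function(predictions, mse) {
  predictions <- as.matrix(predictions)
  stopifnot(ncol(predictions) == length(mse), all(mse >= 0))
  if (any(mse == 0)) {
    pos <- mse[mse > 0]
    if (!length(pos)) pos <- 1
    mse[mse == 0] <- min(pos) * 1e-3
    warning("zero member MSE replaced by smallest positive MSE x 1e-3")
  }
  w <- 1 / mse
  as.numeric(predictions %*% w) / sum(w)
}

#' Ensemble gap-filling of one location
#'
#' Trains `K` ensemble members with different split seeds and combines their
#' daily predictions with inverse test-MSE weights.
#'
#' @param features a [feature_table()] for the location.
#' @param K ensemble size.
#' @param seed base seed; member k uses `seed + k`.
#' @param ... passed to [train_member()].
#' @return list of class `ensemble_prediction`: `day_index`, `f` (ensemble
#'   daily efflux, umol m-2 s-1), `member_mse`, `member_pred` (matrix),
#'   `spread` (per-day sd across members).
#' @export
ensemble_fill <- function(features, K = 100L, seed = 1L, ...) {
  if (K < 2) stop("ensemble needs K >= 2 members", call. = FALSE)
  members <- lapply(seq_len(K), function(k) {
    train_member(features, split_seed = seed + k, ...)
  })
  pred <- vapply(members, predict_member, numeric(nrow(features)),
                 features = features)
  mse <- vapply(members, function(m) m$mse_test, numeric(1))
  structure(list(day_index = features$day_index,
                 f = ensemble_weighted(pred, mse),
                 member_mse = mse, member_pred = pred,
                 spread = apply(pred, 1, stats::sd)),
            class = "ensemble_prediction")
}

#' Convert a daily-mean efflux to a daily carbon flux
#'
#' `gC m-2 d-1 = umol m-2 s-1 x 12e-6 x 3600 x 24` (molar mass of carbon
#' over the seconds of a day).
#'
#' @param flux daily-mean efflux (umol m-2 s-1).
#' @return gC m-2 d-1.
#' @export
daily_to_gC <- function(flux) flux * 12e-6 * 86400

#' Integrate gap-filled daily fluxes to seasonal and annual budgets
#'
#' Sums each location's gap-filled daily carbon flux over August--July
#' budget years and reports the cross-location mean with its standard error
#' (sd / sqrt(n)). Seasonal daily means (dry = January--April, wet =
#' May--December) are computed from the spatial-mean daily series over
#' complete budget years. Partial years are reported with their coverage
#' fraction and excluded from the means by default.
#'
#' @param daily data.frame: `site_id`, `day_index`, `flux` (umol m-2 s-1,
#'   complete per site), plus `budget_year` and `month` (or a `start_year`
#'   to derive them).
#' @param start_year used to derive calendar columns when absent.
#' @param min_coverage fraction of the 365 days a year must have to enter
#'   the cross-location statistics.
#' @return object of class `carbon_budget`: `per_location` (site x year
#'   integrals, gC m-2 yr-1, with `coverage`), `annual` (year, mean, se, n),
#'   `seasonal` (dry/wet daily means, gC m-2 d-1).
#' @export
integrate_annual <- function(daily, start_year = 2013L, min_coverage = 0.999) {
  if (!all(c("budget_year", "month") %in% names(daily))) {
    cal <- sim_calendar(daily$day_index, start_year)
    daily$budget_year <- cal$budget_year
    daily$month <- cal$month
  }
  daily$gC <- daily_to_gC(daily$flux)

  per <- do.call(rbind, lapply(split(daily, list(daily$site_id,
                                                 daily$budget_year),
                                     drop = TRUE), function(d) {
    data.frame(site_id = d$site_id[1], budget_year = d$budget_year[1],
               annual_gC = sum(d$gC), n_days = nrow(d),
               coverage = nrow(d) / 365)
  }))
  rownames(per) <- NULL

  complete <- per[per$coverage >= min_coverage, ]
  annual <- do.call(rbind, lapply(split(complete, complete$budget_year),
                                  function(d) {
    data.frame(budget_year = d$budget_year[1],
               mean_gC = mean(d$annual_gC),
               se_gC = stats::sd(d$annual_gC) / sqrt(nrow(d)),
               n_locations = nrow(d))
  }))
  rownames(annual) <- NULL

  ## seasonal daily means from the spatial-mean series over complete years
  yrs <- annual$budget_year
  sub <- daily[daily$budget_year %in% yrs, ]
  spm <- stats::aggregate(gC ~ day_index + month, data = sub, FUN = mean)
  dry <- is_dry_season(spm$month)
  seasonal <- data.frame(
    season = c("dry", "wet"),
    mean_gC_day = c(mean(spm$gC[dry]), mean(spm$gC[!dry])),
    se_gC_day = c(stats::sd(spm$gC[dry]) / sqrt(sum(dry)),
                  stats::sd(spm$gC[!dry]) / sqrt(sum(!dry)))
  )
  structure(list(per_location = per, annual = annual, seasonal = seasonal),
            class = "carbon_budget")
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat("<carbon_budget> annual integrals (gC m-2 yr-1, Aug-Jul):\n")
  for (i in seq_len(nrow(x$annual))) {
    cat(sprintf("  %d: %.0f (+/- %.0f SE, n = %d)\n",
                x$annual$budget_year[i], x$annual$mean_gC[i],
                x$annual$se_gC[i], x$annual$n_locations[i]))
  }
  cat(sprintf("  seasonal daily means: dry %.2f, wet %.2f gC m-2 d-1\n",
              x$seasonal$mean_gC_day[1], x$seasonal$mean_gC_day[2]))
  invisible(x)
}
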