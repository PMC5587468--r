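#' CSV and JSON writers/readers for the pipeline artifacts
#'
#' All tables are written as UTF-8 CSV with dot decimals and ISO-8601
#' timestamps; scalar results are written as JSON. Writers and readers
#' round-trip losslessly.
#'
#' @name soilresp-io
NULL

#' @rdname soilresp-io
#' @param trace_set a `trace_set` from [synthesize_traces()].
#' @param path output file.
#' @param start_year nominal start year for timestamps.
#' @export
write_traces_csv <- function(trace_set, path, start_year = 2013L) {
  tr <- trace_set$traces
  out <- data.frame(
    trace_id = tr$trace_id, site_id = tr$site_id,
    timestamp = sim_timestamp(tr$time, start_year),
    elapsed_s = tr$elapsed_s,
    co2_umol_mol = tr$co2,
    t_chamber_C = tr$t_chamber,
    pressure_Pa = tr$pressure
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname soilresp-io
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname soilresp-io
#' @param env an `env_series`.
#' @export
write_env_csv <- function(env, path, start_year = 2013L) {
  out <- cbind(timestamp = sim_timestamp(env$time, start_year),
               as.data.frame(env))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname soilresp-io
#' @param df any data.frame artifact (sites, daily environment, fluxes,
#'   pulses, composites...).
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname soilresp-io
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname soilresp-io
#' @param x list of scalars/vectors.
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the whole analysis chain on synthetic data
#'
#' Executes simulate -> flux fitting -> QC -> moisture fit -> pulse
#' detection -> variability/diurnal statistics -> ensemble gap-filling ->
#' budget integration -> spatial ANOVA, writing every artifact (CSV/JSON)
#' plus a manifest echoing the fully resolved configuration and seed. The
#' scale knobs (`members`, `gapfill_sites`) keep desk-scale runs tractable.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @param members ANN ensemble size per location.
#' @param gapfill_sites how many manual collars to gap-fill (first n).
#' @return invisibly, a list with the in-memory results (`budget`,
#'   `moisture`, `pulses`, `anova`, paths).
#' @export
run_pipeline <- function(config, out_dir, members = 10L, gapfill_sites = 6L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  env <- generate_env(config)
  sites <- make_collar_sites(config)
  latent <- generate_latent_flux(env, sites, config)
  env_d <- env_daily(env)
  manual <- synthesize_traces(latent, config, system = "manual")

  write_env_csv(env, p("env.csv"), config$start_year)
  write_table_csv(env_d, p("env_daily.csv"))
  write_table_csv(as.data.frame(sites), p("sites.csv"))
  write_traces_csv(manual, p("traces.csv"), config$start_year)
  write_table_csv(manual$meta, p("truth.csv"))

  est <- fit_fluxes(manual)
  est <- qc_filter(est, system = "manual")
  est <- apply_jump_filter(est)
  write_table_csv(est, p("fluxes.csv"))
  kept <- est[est$kept, ]

  ## moisture response on daily spatial means
  day_mean <- stats::aggregate(flux ~ day_index, data = kept, FUN = mean)
  day_mean$swc <- env_d$swc[match(day_mean$day_index, env_d$day_index)]
  mr <- fit_moisture_quadratic(day_mean$swc, day_mean$flux, robust = TRUE)
  write_json_result(list(a = mr$a, b = mr$b, c = mr$c, optimum = mr$optimum,
                         r2 = mr$r2, rmse = mr$rmse), p("moisture_fit.json"))

  ## pulses from the automated (sub-daily) record
  auto_ids <- sites$site_id[sites$system == "automated"]
  auto_flux <- rowMeans(latent$flux[, auto_ids, drop = FALSE])
  pulses <- detect_pulses(env$time, auto_flux, env$swc)
  write_table_csv(pulses, p("pulses.csv"))
  preg <- if (nrow(pulses) >= 3) pulse_regression(pulses) else NULL

  ## variability statistics on the manual campaign matrix
  M <- flux_matrix(kept, sites)
  day_swc <- env_d$swc[match(as.numeric(colnames(M$f)), env_d$day_index)]
  wet <- day_swc > 0.35
  acf_df <- temporal_acf(M)
  sv <- semivariogram(M)
  cv_all <- cv_stats(M)
  cv_wet <- cv_stats(M, stratum = wet)
  cv_dry <- cv_stats(M, stratum = !wet)
  write_table_csv(acf_df, p("acf.csv"))
  write_table_csv(sv, p("semivariogram.csv"))
  write_json_result(list(
    spatial_cv = cv_all$spatial_cv,
    temporal_cv_median = stats::median(cv_all$temporal_cv, na.rm = TRUE),
    temporal_cv_median_wet = stats::median(cv_wet$temporal_cv, na.rm = TRUE),
    temporal_cv_median_dry = stats::median(cv_dry$temporal_cv, na.rm = TRUE)
  ), p("variability.json"))

  ## dry-season diurnal composites (automated record)
  dry_mask <- is_dry_season(env$month)
  comp_f <- composite_diurnal(env$time, auto_flux, dry_mask)
  comp_t <- composite_diurnal(env$time, env$t_soil, dry_mask)
  write_table_csv(data.frame(hour = comp_f$hour, flux = comp_f$mean,
                             flux_norm = comp_f$normalized,
                             t_soil = comp_t$mean,
                             t_soil_norm = comp_t$normalized),
                  p("diurnal.csv"))

  ## gap-filling + budget
  fill_ids <- utils::head(sites$site_id[sites$system == "manual"],
                          gapfill_sites)
  filled <- list()
  for (sid in fill_ids) {
    ft <- feature_table(env_d, kept[kept$site_id == sid, ])
    ep <- ensemble_fill(ft, K = members, seed = config$seed)
    filled[[sid]] <- data.frame(site_id = sid, day_index = ep$day_index,
                                flux = ep$f, ensemble_sd = ep$spread)
  }
  filled <- do.call(rbind, filled)
  write_table_csv(filled, p("filled_daily.csv"))
  budget <- integrate_annual(filled, start_year = config$start_year)
  write_json_result(list(
    annual = budget$annual, seasonal = budget$seasonal
  ), p("budget.json"))

  ## spatial ANOVA on moisture-detrended residuals
  res <- residualize(kept, mr, env_d)
  atab <- anova_decompose(res, sites)
  write_table_csv(as.data.frame(atab), p("anova.csv"))

  cfg_echo <- unclass(config)
  cfg_echo$dry_event_days <- cfg_echo$dry_event_days %||% list()
  write_json_result(list(config = cfg_echo, seed = config$seed,
                         members = members, gapfill_sites = gapfill_sites),
                    p("manifest.json"))
  invisible(list(budget = budget, moisture = mr, pulses = pulses,
                 pulse_regression = preg, anova = atab, out_dir = out_dir))
}
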