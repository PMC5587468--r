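#' Simulation configuration
#'
#' Builds the configuration object that controls every stage of the synthetic
#' chamber-network generator: the environmental drivers, the latent per-collar
#' efflux field, and the raw chamber concentration traces. Defaults emulate a
#' seasonal (January--April dry season) tropical moist forest monitored by 4
#' automated collars on a 20 x 20 m square and 32 manual collars at roughly
#' 20 m spacing, over `n_years` complete August--July budget years.
#'
#' @param n_years number of complete August--July budget years (>= 1).
#' @param seed integer master seed; all generator randomness derives from it.
#' @param start_year nominal calendar year of the 1 June simulation start.
#' @param swc_wet wet-season volumetric water content plateau (cm3/cm3).
#' @param swc_dry_min dry-season baseline minimum (cm3/cm3).
#' @param rain_rate_wet,rain_rate_dry rain-event rates (events per day) of the
#'   marked Poisson rain process in wet and dry season.
#' @param rain_depth_wet,rain_depth_dry mean event depths (mm, exponential).
#' @param swc_per_mm soil water content jump per mm of rain (cm3/cm3/mm).
#' @param swc_recession_days e-folding time of soil moisture recession toward
#'   the seasonal baseline after a rain event (days).
#' @param swc_diurnal_amp dry-season diurnal soil moisture drawdown
#'   (half-range, cm3/cm3).
#' @param quad_a,quad_b,quad_c coefficients of the latent quadratic moisture
#'   response flux = a + b swc + c swc^2 (umol m-2 s-1); must be concave
#'   (c < 0). Defaults place the vertex at swc = 0.45 with peak 4.6.
#' @param diurnal_amplitude dry-season diurnal efflux amplitude
#'   (peak-to-trough, umol m-2 s-1), peaking at 08:00.
#' @param pulse_gain relative flux rise per relative soil-moisture rise of a
#'   rewetting pulse (dimensionless; 5 means the flux doubles for a 20% rise).
#' @param pulse_decay_days e-folding decay of a pulse (days).
#' @param site_cv coefficient of variation of the lognormal among-collar site
#'   multiplier u(x).
#' @param latent_noise_cv coefficient of variation of the multiplicative
#'   lognormal noise on the latent 30-min efflux.
#' @param annual_targets per-budget-year spatial-mean annual efflux targets
#'   (gC m-2 yr-1) that the latent field is rescaled to; length `n_years`.
#' @param t_soil_mean,t_soil_annual_amp,t_soil_diurnal_dry,t_soil_diurnal_wet
#'   soil temperature model: mean, annual harmonic amplitude and dry/wet
#'   season diurnal amplitudes (degC, half-range); diurnal peak 13:30.
#' @param t_soil_noise_sd additive soil temperature noise sd (degC).
#' @param trace_noise_sd additive CO2 noise on chamber traces (umol mol-1).
#' @param trace_ambient ambient CO2 mole fraction at chamber close
#'   (umol mol-1).
#' @param k_sat_auto,k_sat_manual chamber saturation constants (s-1) of the
#'   exponential concentration build-up for the two systems.
#' @param corrupt_fraction fraction of traces corrupted (leak, spike or
#'   drift) to exercise quality control.
#' @param vol_area_ratio effective chamber system volume-to-area ratio V/A (m).
#' @param auto_diameter_cm,manual_diameter_cm collar inner diameters (cm).
#' @param n_manual number of manual collars (27 plot rings + 5 gap rings).
#' @param dry_event_days optional numeric vector of simulation day indices at
#'   which dry-season rain events are scheduled deterministically; when given
#'   it replaces the Poisson dry-season rain process (used to inject a known
#'   set of rewetting pulses).
#' @param dry_event_depth_mm depths (mm) for scheduled dry-season events
#'   (recycled to `length(dry_event_days)`).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_years = 3L,
                       seed = 1L,
                       start_year = 2013L,
                       swc_wet = 0.45,
                       swc_dry_min = 0.20,
                       rain_rate_wet = 1 / 2.5,
                       rain_rate_dry = 1 / 12,
                       rain_depth_wet = 11,
                       rain_depth_dry = 7,
                       swc_per_mm = 0.003,
                       swc_recession_days = 2,
                       swc_diurnal_amp = 0.002,
                       quad_a = 4.6 - 30 * 0.45^2,
                       quad_b = 2 * 0.45 * 30,
                       quad_c = -30,
                       diurnal_amplitude = 0.6,
                       pulse_gain = 5,
                       pulse_decay_days = 2,
                       site_cv = 0.20,
                       latent_noise_cv = 0.10,
                       annual_targets = c(1591, 1602, 1646),
                       t_soil_mean = 25.8,
                       t_soil_annual_amp = 1.3,
                       t_soil_diurnal_dry = 1.5,
                       t_soil_diurnal_wet = 0.4,
                       t_soil_noise_sd = 0.15,
                       trace_noise_sd = 0.8,
                       trace_ambient = 400,
                       k_sat_auto = 4e-4,
                       k_sat_manual = 1e-4,
                       corrupt_fraction = 0,
                       vol_area_ratio = 0.20,
                       auto_diameter_cm = 11.4,
                       manual_diameter_cm = 25,
                       n_manual = 32L,
                       dry_event_days = NULL,
                       dry_event_depth_mm = 8) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  chk_pos <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("sim_config parameter '%s' must be finite and positive",
                   name), call. = FALSE)
    }
  }
  chk_nonneg <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("sim_config parameter '%s' must be finite and >= 0", name),
           call. = FALSE)
    }
  }
  if (cfg$n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  for (p in c("rain_depth_wet", "rain_depth_dry", "swc_per_mm",
              "swc_recession_days", "pulse_decay_days", "vol_area_ratio",
              "auto_diameter_cm", "manual_diameter_cm")) chk_pos(p)
  for (p in c("rain_rate_wet", "rain_rate_dry", "swc_diurnal_amp",
              "diurnal_amplitude", "pulse_gain", "site_cv", "latent_noise_cv",
              "t_soil_noise_sd", "trace_noise_sd", "corrupt_fraction")) {
    chk_nonneg(p)
  }
  if (cfg$quad_c >= 0) {
    stop("latent moisture quadratic must be concave (quad_c < 0)",
         call. = FALSE)
  }
  if (any(!is.finite(cfg$annual_targets)) || any(cfg$annual_targets <= 0)) {
    stop("annual_targets must be finite and positive", call. = FALSE)
  }
  if (length(cfg$annual_targets) < cfg$n_years) {
    cfg$annual_targets <- rep_len(cfg$annual_targets, cfg$n_years)
  }
  if (cfg$corrupt_fraction > 1) {
    stop("corrupt_fraction must be in [0, 1]", call. = FALSE)
  }
  if (!(cfg$swc_wet > cfg$swc_dry_min)) {
    stop("swc_wet must exceed swc_dry_min", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_years, "budget year(s), seed", x$seed, "\n")
  cat("  swc plateaus:", x$swc_dry_min, "-", x$swc_wet,
      "| quadratic vertex:", round(-x$quad_b / (2 * x$quad_c), 3), "\n")
  cat("  annual targets (gC m-2 yr-1):",
      paste(x$annual_targets[seq_len(x$n_years)], collapse = ", "), "\n")
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown sim_config keys in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(sim_config, vals)
}
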