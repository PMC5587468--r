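#' @title Simulation calendar (365-day, no leap days)
#' @description
#' The simulation runs on a fixed 365-day calendar with no leap days, starting
#' on 1 June of a nominal start year (the first month of record). Budget years
#' run August through July. All helpers below map a 0-based day index on this
#' calendar to year / month / day-of-year components.
#' @name sim-calendar
#' @keywords internal
NULL

.MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_CUM <- cumsum(c(0L, .MONTH_LEN))   # day-of-year offset before month m
.DOY_JUN1 <- 152L                         # 1 June in a 365-day year
.DOY_AUG1 <- 213L                         # 1 August

#' Calendar components for simulation day indices
#'
#' @param day_index integer vector, 0-based days since simulation start
#'   (1 June of `start_year`).
#' @param start_year nominal calendar year of the simulation start.
#' @return data.frame with columns `day_index`, `year`, `doy` (1..365),
#'   `month`, `mday`, and `budget_year` (August--July year label: the year in
#'   which the budget year starts).
#' @export
sim_calendar <- function(day_index, start_year = 2013L) {
  stopifnot(all(day_index >= 0))
  abs_doy0 <- (.DOY_JUN1 - 1L) + as.integer(day_index)  # 0-based absolute doy
  year <- start_year + abs_doy0 %/% 365L
  doy <- abs_doy0 %% 365L + 1L
  month <- findInterval(doy - 1L, .MONTH_CUM[-length(.MONTH_CUM)])
  mday <- doy - .MONTH_CUM[month]
  data.frame(
    day_index = as.integer(day_index),
    year = year, doy = doy, month = month, mday = mday,
    budget_year = ifelse(doy >= .DOY_AUG1, year, year - 1L)
  )
}

#' ISO-8601 timestamp strings on the simulation calendar
#'
#' @param time fractional days since simulation start.
#' @param start_year nominal start year.
#' @return character vector `YYYY-MM-DDTHH:MM:SS`.
#' @export
sim_timestamp <- function(time, start_year = 2013L) {
  d <- floor(time + 1e-9)
  cal <- sim_calendar(d, start_year)
  frac <- time - d
  secs <- round(frac * 86400)
  hh <- secs %/% 3600
  mm <- (secs %% 3600) %/% 60
  ss <- secs %% 60
  sprintf("%04d-%02d-%02dT%02d:%02d:%02d", cal$year, cal$month, cal$mday,
          hh, mm, ss)
}

#' Dry-season indicator (January through April)
#'
#' @param month integer month 1..12.
#' @return logical; TRUE for months 1-4 (the dry season of a BCI-like climate).
#' @export
is_dry_season <- function(month) month >= 1L & month <= 4L

#' Number of days the simulation must cover
#'
#' A June--July spin-up (61 days) plus `n_years` complete August--July years.
#' @param n_years number of complete budget years.
#' @return integer number of days.
#' @keywords internal
sim_n_days <- function(n_years) 61L + 365L * as.integer(n_years)
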