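#' Core columns of a half-hourly flux table
#'
#' The package's spine is an ordinary tibble of half-hourly records with a
#' `timestamp` column (POSIXct, local standard time, end-of-interval
#' convention) and the measured variables in fixed units:
#' `nee` (µmol m⁻² s⁻¹, uptake negative), `rg` (W m⁻²), `ta` (°C), `ts` (°C),
#' `rh` (%), `vpd` (kPa), `precip` (mm per half hour), `ustar` (m s⁻¹) and
#' `pa` (Pa). Processing stages append `qc_flag`, `fill_flag`, `reco`, `gpp`
#' and friends; every function takes the tibble first and returns a tibble,
#' so stages chain with the pipe.
#'
#' @name half_hourly
#' @keywords internal
NULL

hh_required_cols <- c("timestamp", "nee", "rg", "ta", "ts", "rh", "vpd",
                      "precip", "ustar", "pa")

assert_half_hourly <- function(series, cols = c("timestamp", "nee")) {
  if (!is.data.frame(series)) {
    abort("`series` must be a data frame of half-hourly records.")
  }
  missing_cols <- setdiff(cols, names(series))
  if (length(missing_cols) > 0) {
    abort(paste0("`series` is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(series)
}

#' Season calendar for a semiarid year
#'
#' Returns the labelled, non-overlapping month-day intervals that partition
#' the year into the four seasons used for carbon accounting: the wet season,
#' the wet-dry transition, the dry season and the dry-wet transition (which
#' wraps the year boundary). Boundaries are configurable; the defaults place
#' the wet season between mid January and the end of May, as at semiarid
#' sites of northeast Brazil.
#'
#' @param wet,wet_dry,dry,dry_wet Character vectors of length 2 giving the
#'   first and last day of each season as `"mm-dd"`. `dry_wet` may wrap the
#'   year boundary.
#' @return A tibble with columns `season`, `start`, `end` (month-day strings).
#' @export
#' @examples
#' season_calendar()
season_calendar <- function(wet = c("01-15", "05-31"),
                            wet_dry = c("06-01", "07-31"),
                            dry = c("08-01", "11-30"),
                            dry_wet = c("12-01", "01-14")) {
  cal <- tibble(
    season = c("wet", "wet-dry", "dry", "dry-wet"),
    start = c(wet[1], wet_dry[1], dry[1], dry_wet[1]),
    end = c(wet[2], wet_dry[2], dry[2], dry_wet[2])
  )
  # check the union covers all days exactly once on a non-leap template year
  days <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  hits <- vapply(format(days, "%m-%d"), function(md) {
    sum(md_in_interval(md, cal$start, cal$end))
  }, integer(1))
  if (any(hits != 1L)) {
    abort("season calendar must cover every day of the year exactly once")
  }
  cal
}

# is month-day string md inside [start, end], allowing year wrap-around;
# recycles either the dates or the interval bounds
md_in_interval <- function(md, start, end) {
  wrap <- start > end
  (!wrap & md >= start & md <= end) | (wrap & (md >= start | md <= end))
}

#' Assign a season label to each timestamp
#'
#' @param timestamp POSIXct or Date vector.
#' @param calendar A season calendar, see [season_calendar()].
#' @return Character vector of season labels.
#' @export
assign_season <- function(timestamp, calendar = season_calendar()) {
  md <- format(as.Date(timestamp, tz = attr_tz(timestamp)), "%m-%d")
  out <- rep(NA_character_, length(md))
  for (i in seq_len(nrow(calendar))) {
    hit <- md_in_interval(md, calendar$start[i], calendar$end[i])
    out[hit] <- calendar$season[i]
  }
  out
}

attr_tz <- function(x) {
  tz <- attr(x, "tzone")
  if (is.null(tz) || tz == "") "UTC" else tz
}

# decimal hour of day of the end-of-interval timestamp
clock_hour <- function(timestamp) {
  lubridate::hour(timestamp) + lubridate::minute(timestamp) / 60
}

# population covariance (1/N normalisation)
pop_cov <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y)))
}

days_in_year <- function(year) {
  if (lubridate::leap_year(year)) 366L else 365L
}

#' Half-hourly timestamp grid for one calendar year
#'
#' End-of-interval convention: the first record of the year is stamped
#' 00:30 on 1 January and the last 00:00 on 1 January of the next year.
#'
#' @param year Calendar year.
#' @param tz Timezone label (stored, not converted; local standard time).
#' @return POSIXct vector of length 17,520 (17,568 in leap years).
#' @export
hh_grid <- function(year, tz = "UTC") {
  start <- lubridate::make_datetime(year, 1, 1, 0, 30, tz = tz)
  n <- days_in_year(year) * 48L
  start + lubridate::dhours(0.5) * (seq_len(n) - 1L)
}
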