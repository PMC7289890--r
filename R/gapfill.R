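#' Tolerances for marginal distribution sampling
#'
#' Similarity tolerances used to find donor records under comparable
#' meteorological conditions, and the ladder of time windows tried in
#' order when a window yields too few donors.
#'
#' @param rg_tol Global-radiation tolerance (W m⁻², default 50). The
#'   effective tolerance at a record never exceeds 20% of the target's
#'   `rg` (`rg_frac`), so nighttime gaps are matched against nighttime
#'   donors.
#' @param ta_tol Air-temperature tolerance (°C, default 2.5).
#' @param vpd_tol Vapour-pressure-deficit tolerance in hPa (default 5).
#'   The series stores VPD in kPa; the unit is converted here, at this one
#'   documented boundary.
#' @param window_ladder Strictly increasing half-window spans in days
#'   (default 7, 14, 28, 56, 112).
#' @param min_donors Minimum donor count for a valid fill (default 2).
#' @param rg_frac Fractional cap on the radiation tolerance (default 0.2).
#' @return An object of class `mds_tolerances`.
#' @export
mds_tolerances <- function(rg_tol = 50, ta_tol = 2.5, vpd_tol = 5,
                           window_ladder = c(7, 14, 28, 56, 112),
                           min_donors = 2, rg_frac = 0.2) {
  if (any(c(rg_tol, ta_tol, vpd_tol) <= 0)) {
    abort("all tolerances must be > 0")
  }
  if (any(diff(window_ladder) <= 0)) {
    abort("`window_ladder` must be strictly increasing")
  }
  structure(list(rg_tol = rg_tol, ta_tol = ta_tol,
                 vpd_tol_kpa = vpd_tol / 10, window_ladder = window_ladder,
                 min_donors = as.integer(min_donors), rg_frac = rg_frac),
            class = "mds_tolerances")
}

#' Fill missing NEE by marginal distribution sampling
#'
#' For each missing NEE record, in order of available information:
#' \enumerate{
#'   \item if the record's `rg`, `ta` and `vpd` are all present, the fill is
#'     the mean NEE of records within all three tolerances inside a ±7 day
#'     window (exploiting the covariation of fluxes with meteorology);
#'   \item if only `rg` is present, only the radiation tolerance is used;
#'   \item with no meteorology, the fill is the mean of records at the same
#'     clock time (±1 hour) of the adjacent day(s) (exploiting temporal
#'     autocorrelation).
#' }
#' When a window yields fewer than `min_donors` donors the window widens
#' along the ladder and the search repeats; when a method is exhausted the
#' next one is tried, ending with a same-clock-time mean over the whole
#' series. Fill quality is graded `A` (method 1, window ≤ 14 d), `B`
#' (method 1 beyond 14 d, or method 2 within 14 d) or `C` (anything else).
#' Observed values are never altered.
#'
#' @param series Half-hourly tibble with `timestamp`, `nee`, `rg`, `ta`,
#'   `vpd` (the met columns may themselves contain gaps; see
#'   [fill_meteorology()]).
#' @param tol An [mds_tolerances()] object.
#' @return The series with `nee` filled and columns `fill_flag`
#'   (`observed`/`A`/`B`/`C`), `fill_method` (`full-met`/`rg-only`/
#'   `diurnal-mean`), `fill_window` (half-window in days) and `fill_n_donors`
#'   added. Errors if the series holds no valid NEE at all.
#' @export
mds_fill <- function(series, tol = mds_tolerances()) {
  assert_half_hourly(series, c("timestamp", "nee", "rg", "ta", "vpd"))
  stopifnot(inherits(tol, "mds_tolerances"))
  n <- nrow(series)
  nee <- series$nee
  valid <- is.finite(nee)
  if (!any(valid)) abort("series has no valid NEE anywhere: unfillable")
  gaps <- which(!valid)

  day_num <- as.numeric(difftime(series$timestamp, series$timestamp[1],
                                 units = "days"))
  clock <- clock_hour(series$timestamp)
  has_rg <- is.finite(series$rg)
  has_met <- has_rg & is.finite(series$ta) & is.finite(series$vpd)

  fill_flag <- ifelse(valid, "observed", NA_character_)
  fill_method <- rep(NA_character_, n)
  fill_window <- rep(NA_real_, n)
  fill_n <- rep(NA_integer_, n)
  filled <- nee

  iii_ladder <- sort(unique(c(1, 2, 4, tol$window_ladder)))

  for (i in gaps) {
    res <- NULL
    if (has_met[i]) {
      res <- mds_scan(i, filled_src = nee, valid = valid, day_num = day_num,
                      series = series, tol = tol, mode = "full-met")
    }
    if (is.null(res) && has_rg[i]) {
      res <- mds_scan(i, filled_src = nee, valid = valid, day_num = day_num,
                      series = series, tol = tol, mode = "rg-only")
    }
    if (is.null(res)) {
      # method iii: same clock time (±1 h) in adjacent days, widening
      for (w in iii_ladder) {
        don <- which(valid & abs(day_num - day_num[i]) <= w &
                       circ_hour_diff(clock, clock[i]) <= 1 &
                       seq_len(n) != i)
        if (length(don) >= tol$min_donors) {
          res <- list(value = mean(nee[don]), method = "diurnal-mean",
                      window = w, n = length(don))
          break
        }
      }
      if (is.null(res)) {
        don <- which(valid & circ_hour_diff(clock, clock[i]) <= 1)
        if (length(don) == 0) don <- which(valid)
        res <- list(value = mean(nee[don]), method = "diurnal-mean",
                    window = Inf, n = length(don))
      }
    }
    filled[i] <- res$value
    fill_method[i] <- res$method
    fill_window[i] <- res$window
    fill_n[i] <- res$n
    fill_flag[i] <-
      if (res$method == "full-met" && res$window <= 14) "A"
      else if ((res$method == "full-met" && res$window > 14) ||
               (res$method == "rg-only" && res$window <= 14)) "B"
      else "C"
  }

  out <- series
  out$nee <- filled
  out$fill_flag <- fill_flag
  out$fill_method <- fill_method
  out$fill_window <- fill_window
  out$fill_n_donors <- fill_n
  attr(out, "n_filled") <- length(gaps)
  out
}

# donor scan for MDS methods i and ii; returns NULL if the ladder fails
mds_scan <- function(i, filled_src, valid, day_num, series, tol, mode) {
  rg_tol_i <- min(tol$rg_tol, tol$rg_frac * abs(series$rg[i]))
  for (w in tol$window_ladder) {
    cand <- which(valid & abs(day_num - day_num[i]) <= w)
    cand <- cand[cand != i]
    ok <- abs(series$rg[cand] - series$rg[i]) <= rg_tol_i &
      is.finite(series$rg[cand])
    if (mode == "full-met") {
      ok <- ok &
        is.finite(series$ta[cand]) & is.finite(series$vpd[cand]) &
        abs(series$ta[cand] - series$ta[i]) <= tol$ta_tol &
        abs(series$vpd[cand] - series$vpd[i]) <= tol$vpd_tol_kpa
    }
    don <- cand[which(ok)]
    if (length(don) >= tol$min_donors) {
      return(list(value = mean(filled_src[don]), method = mode,
                  window = w, n = length(don)))
    }
  }
  NULL
}

# absolute clock-time difference on the 24 h circle
circ_hour_diff <- function(h, h0) {
  d <- abs(h - h0)
  pmin(d, 24 - d)
}

#' Fill gaps in driver meteorology
#'
#' The gap-filling of NEE needs complete drivers. Missing values of the
#' meteorological columns are filled by the diurnal-mean logic (mean of
#' records at the same clock time ±1 h in adjacent days, widening the day
#' window), falling back to a same-clock-time climatology over the whole
#' series when a variable is missing in bulk (> `max_gap_frac`), with a
#' warning.
#'
#' @param series Half-hourly tibble.
#' @param vars Columns to fill (default `rg`, `ta`, `vpd`, `ts`, `rh`).
#' @param max_gap_frac Gap fraction per variable above which the
#'   climatology fallback warning is raised (default 0.2).
#' @return The series with met gaps filled; attribute `met_fill_counts`
#'   records how many values were filled per variable.
#' @export
fill_meteorology <- function(series, vars = c("rg", "ta", "vpd", "ts", "rh"),
                             max_gap_frac = 0.2) {
  assert_half_hourly(series, "timestamp")
  vars <- intersect(vars, names(series))
  day_num <- as.numeric(difftime(series$timestamp, series$timestamp[1],
                                 units = "days"))
  clock <- clock_hour(series$timestamp)
  counts <- integer(0)
  out <- series
  for (v in vars) {
    x <- out[[v]]
    miss <- which(!is.finite(x))
    counts[v] <- length(miss)
    if (length(miss) == 0) next
    if (length(miss) / length(x) > max_gap_frac) {
      warn(sprintf("'%s' has %.0f%% missing; filling with a clock-time climatology",
                   v, 100 * length(miss) / length(x)))
    }
    valid <- is.finite(x)
    if (!any(valid)) {
      warn(sprintf("'%s' has no valid data at all; left missing", v))
      next
    }
    for (i in miss) {
      done <- FALSE
      for (w in c(1, 2, 4, 7, 14, 28)) {
        don <- which(valid & abs(day_num - day_num[i]) <= w &
                       circ_hour_diff(clock, clock[i]) <= 1)
        if (length(don) >= 2) {
          x[i] <- mean(x[don])
          done <- TRUE
          break
        }
      }
      if (!done) {
        don <- which(valid & circ_hour_diff(clock, clock[i]) <= 1)
        if (length(don) == 0) don <- which(valid)
        x[i] <- mean(x[don])
      }
    }
    out[[v]] <- x
  }
  attr(out, "met_fill_counts") <- counts
  out
}
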