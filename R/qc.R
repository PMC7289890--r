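#' Flag nighttime records
#'
#' Nighttime is defined by low incoming global radiation. Records with a
#' missing `rg` get an unknown (`NA`) flag.
#'
#' @param series Half-hourly tibble with an `rg` column (W m⁻²).
#' @param rg_threshold Radiation threshold in W m⁻² (default 10).
#' @return Logical vector: `TRUE` at night, `NA` where `rg` is missing.
#' @export
flag_nighttime <- function(series, rg_threshold = 10) {
  assert_half_hourly(series, "rg")
  ifelse(is.finite(series$rg), series$rg < rg_threshold, NA)
}

# centred moving median that tolerates missing values; x has no NAs here
moving_median <- function(x, window) {
  if (length(x) < window) return(rep(median(x), length(x)))
  stats::runmed(x, window, endrule = "median")
}

# centred moving MAD (unscaled median absolute deviation)
moving_mad <- function(x, window) {
  if (length(x) < window) {
    return(rep(median(abs(x - median(x))), length(x)))
  }
  zoo::rollapply(x, window, function(v) median(abs(v - median(v))),
                 fill = NA, partial = TRUE)
}

#' Despike a half-hourly series with a moving-median filter
#'
#' Separates the series into a smooth part (centred moving median) and a
#' residual part; records whose residual exceeds `z_threshold` times the
#' Gaussian-consistent scaled MAD (1.4826 × moving MAD) of the residuals
#' are spikes. Flagged records are replaced by the missing value (to be
#' gap-filled later, never interpolated) and the filter is re-applied
#' until no new spikes are found or `max_passes` is reached. Windows with
#' zero MAD (constant data) flag nothing. Series shorter than the window
#' fall back to a single global-median pass.
#'
#' Day and night records are despiked as separate streams whenever a
#' nighttime flag is available (the flux diurnal cycle would otherwise
#' dominate the residuals and the daily extremes would be mistaken for
#' spikes); pass `night = FALSE` to force a single stream.
#'
#' @param series Half-hourly tibble.
#' @param column Column to despike (default `"nee"`).
#' @param window Window length in half hours (odd, >= 3; default 49).
#' @param z_threshold Spike threshold in scaled-MAD multiples (default 7).
#' @param max_passes Maximum filter passes (default 10).
#' @param night Logical nighttime mask, `NULL` to derive it from `rg` when
#'   present (see [flag_nighttime()]), or `FALSE` for a single stream.
#' @return The series with spikes blanked in `column`, a `qc_flag` column
#'   (0 ok, 1 spike, 9 missing input) and attribute `spike_mask` (logical).
#' @export
despike_moving_median <- function(series, column = "nee", window = 49,
                                  z_threshold = 7, max_passes = 10,
                                  night = NULL) {
  assert_half_hourly(series, column)
  if (window < 3 || window %% 2 == 0) abort("`window` must be odd and >= 3")
  if (z_threshold <= 0) abort("`z_threshold` must be > 0")
  x <- series[[column]]
  if (is.null(night)) {
    night <- if ("rg" %in% names(series)) flag_nighttime(series) else FALSE
  }
  if (length(night) == 1) night <- rep(night, length(x))
  missing_in <- !is.finite(x)

  despike_stream <- function(idx_all) {
    spike <- rep(FALSE, length(x))
    for (pass in seq_len(max_passes)) {
      idx <- idx_all[is.finite(x[idx_all]) & !spike[idx_all]]
      if (length(idx) < 3) break
      v <- x[idx]
      resid <- v - moving_median(v, window)
      sig <- 1.4826 * moving_mad(resid, window)
      new_spike <- abs(resid) > z_threshold * sig & sig > 0
      if (!any(new_spike)) break
      spike[idx[new_spike]] <- TRUE
    }
    spike
  }
  streams <- split(seq_along(x), ifelse(is.na(night), FALSE, night))
  spike <- Reduce(`|`, lapply(streams, despike_stream))
  out <- series
  out[[column]][spike] <- NA_real_
  if (!"qc_flag" %in% names(out)) out$qc_flag <- 0L
  out$qc_flag[missing_in & out$qc_flag == 0L] <- 9L
  out$qc_flag[spike] <- 1L
  attr(out, "spike_mask") <- spike
  out
}

#' Friction-velocity threshold by the moving point test
#'
#' Estimates, per season, the friction velocity below which nighttime
#' fluxes are systematically underestimated. Valid nighttime records are
#' binned into air-temperature quantile classes; inside each temperature
#' class the records are binned into u* quantile classes and the threshold
#' of the class is the mean u* of the lowest u* class whose mean NEE
#' reaches `crit` (default 95%) of the mean NEE of all higher u* classes.
#' The season threshold is the median over temperature classes, bounded
#' below by `floor_ms`.
#'
#' @param series Half-hourly tibble with `nee`, `ustar`, `ta`.
#' @param night Logical nighttime mask.
#' @param calendar A [season_calendar()].
#' @param n_ta_classes,n_ustar_classes Number of quantile classes
#'   (defaults 6 and 20).
#' @param crit Saturation criterion (default 0.95).
#' @param floor_ms Lower bound for any threshold (m s⁻¹, default 0.05).
#' @param min_records Minimum valid nighttime records per season
#'   (default 200); seasons below it fall back to `default_threshold`
#'   with a warning.
#' @param default_threshold Fallback threshold (m s⁻¹).
#' @return An object of class `ustar_result`: `thresholds` tibble
#'   (`season`, `threshold`, `n`, `fallback`), the per-class means in
#'   `classes`, and the site validity interval `accepted_range`
#'   (0.18-0.34 m s⁻¹) against which thresholds can be soft-checked.
#' @export
ustar_threshold_mpt <- function(series, night,
                                calendar = season_calendar(),
                                n_ta_classes = 6, n_ustar_classes = 20,
                                crit = 0.95, floor_ms = 0.05,
                                min_records = 200,
                                default_threshold = 0.25) {
  assert_half_hourly(series, c("timestamp", "nee", "ustar", "ta"))
  season <- assign_season(series$timestamp, calendar)
  ok <- !is.na(night) & night & is.finite(series$nee) &
    is.finite(series$ustar) & is.finite(series$ta)
  dat <- tibble(season = season[ok], nee = series$nee[ok],
                ustar = series$ustar[ok], ta = series$ta[ok])
  seasons <- unique(calendar$season)

  class_rows <- list()
  thr_rows <- purrr::map(seasons, function(ssn) {
    d <- dat[dat$season == ssn, ]
    if (nrow(d) < min_records) {
      warn(sprintf(
        "season '%s': %d valid nighttime records (< %d); using default u* threshold %.2f m s⁻¹",
        ssn, nrow(d), min_records, default_threshold))
      return(tibble(season = ssn, threshold = default_threshold,
                    n = nrow(d), fallback = TRUE))
    }
    ta_class <- quantile_class(d$ta, n_ta_classes)
    per_ta <- vapply(seq_len(max(ta_class)), function(k) {
      dk <- d[ta_class == k, ]
      if (nrow(dk) < 2 * n_ustar_classes) return(NA_real_)
      u_class <- quantile_class(dk$ustar, n_ustar_classes)
      cls <- tibble(u_class = u_class, nee = dk$nee, ustar = dk$ustar) %>%
        group_by(.data$u_class) %>%
        summarise(mean_nee = mean(.data$nee),
                  mean_ustar = mean(.data$ustar), .groups = "drop") %>%
        arrange(.data$u_class)
      class_rows[[length(class_rows) + 1L]] <<-
        mutate(cls, season = ssn, ta_class = k)
      kk <- nrow(cls)
      if (kk < 2) return(NA_real_)
      for (i in seq_len(kk - 1)) {
        higher <- mean(cls$mean_nee[(i + 1):kk])
        if (is.finite(higher) && higher != 0 &&
            cls$mean_nee[i] >= crit * higher) {
          return(cls$mean_ustar[i])
        }
      }
      cls$mean_ustar[kk]
    }, numeric(1))
    thr <- median(per_ta, na.rm = TRUE)
    if (!is.finite(thr)) {
      warn(sprintf("season '%s': no temperature class yielded a threshold; using default", ssn))
      return(tibble(season = ssn, threshold = default_threshold,
                    n = nrow(d), fallback = TRUE))
    }
    tibble(season = ssn, threshold = max(thr, floor_ms),
           n = nrow(d), fallback = FALSE)
  })
  structure(list(thresholds = bind_rows(thr_rows),
                 classes = bind_rows(class_rows),
                 accepted_range = c(0.18, 0.34),
                 crit = crit, floor_ms = floor_ms),
            class = "ustar_result")
}

# quantile class labels 1..k (collapses ties in breaks)
quantile_class <- function(x, k) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE, labels = FALSE))
}

#' @export
print.ustar_result <- function(x, ...) {
  cat("u* thresholds (moving point test):\n")
  print(as.data.frame(x$thresholds), row.names = FALSE)
  cat(sprintf("site validity interval: %.2f-%.2f m s⁻¹\n",
              x$accepted_range[1], x$accepted_range[2]))
  invisible(x)
}

#' Reject low-turbulence nighttime fluxes
#'
#' Nighttime NEE measured below the seasonal friction-velocity threshold is
#' replaced by the missing value (and later gap-filled); daytime records are
#' never modified.
#'
#' @param series Half-hourly tibble.
#' @param result A [ustar_threshold_mpt()] result.
#' @param night Logical nighttime mask.
#' @param calendar The [season_calendar()] used for the thresholds.
#' @return The series with rejected `nee` blanked, `qc_flag` set to 2
#'   there, and an attribute `n_rejected`.
#' @export
apply_ustar_filter <- function(series, result, night,
                               calendar = season_calendar()) {
  assert_half_hourly(series, c("timestamp", "nee", "ustar"))
  stopifnot(inherits(result, "ustar_result"))
  season <- assign_season(series$timestamp, calendar)
  thr <- result$thresholds$threshold[match(season, result$thresholds$season)]
  reject <- !is.na(night) & night & is.finite(series$nee) &
    is.finite(series$ustar) & is.finite(thr) & series$ustar < thr
  out <- series
  out$nee[reject] <- NA_real_
  if (!"qc_flag" %in% names(out)) out$qc_flag <- 0L
  out$qc_flag[reject] <- 2L
  attr(out, "n_rejected") <- sum(reject)
  out
}
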