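#' Write a half-hourly table to the CSV exchange dialect
#'
#' Plain comma-separated text with an ISO 8601 timestamp column
#' (`YYYY-MM-DD HH:MM`, local standard time, end-of-interval convention)
#' and a numeric missing-value sentinel (default −9999, the common
#' flux-tower exchange convention). Flag columns survive the round trip.
#'
#' @param series Half-hourly tibble.
#' @param path Output file path.
#' @param sentinel Missing-value sentinel written for `NA` (default −9999).
#' @return `path`, invisibly.
#' @export
write_half_hourly <- function(series, path, sentinel = DRYFLUX_SENTINEL) {
  assert_half_hourly(series, "timestamp")
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M")
  for (v in setdiff(names(out), "timestamp")) {
    if (is.numeric(out[[v]])) {
      out[[v]][!is.finite(out[[v]])] <- sentinel
    } else {
      out[[v]][is.na(out[[v]])] <- as.character(sentinel)
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a half-hourly table from the CSV exchange dialect
#'
#' Reads the dialect written by [write_half_hourly()]: the sentinel is
#' mapped back to `NA`, timestamps are validated (strictly increasing,
#' 30-minute spacing) and missing half hours are inserted as all-missing
#' rows so the returned grid is exactly regular. Duplicate or decreasing
#' timestamps and malformed rows are errors naming the offending lines.
#'
#' @param path CSV file path.
#' @param sentinel Missing-value sentinel (default −9999).
#' @param tz Timezone label for the timestamps (default `"UTC"`, standing
#'   for local standard time).
#' @return A half-hourly tibble on a regular 30-minute grid.
#' @export
read_half_hourly <- function(path, sentinel = DRYFLUX_SENTINEL, tz = "UTC") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE, show_col_types = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed row(s) in ", path, " at line(s): ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  numeric_cols <- c(setdiff(hh_required_cols, "timestamp"), "qc_flag",
                    "reco", "gpp", "reco_model", "veg_index",
                    "fill_window", "fill_n_donors", "f_co2", "s_c")
  for (v in intersect(names(raw), numeric_cols)) {
    if (!is.numeric(raw[[v]])) {
      coerced <- suppressWarnings(as.numeric(raw[[v]]))
      bad <- which(!is.na(raw[[v]]) & is.na(coerced))
      if (length(bad) > 0) {
        abort(paste0("malformed value(s) in column '", v,
                     "' at data row(s): ", paste(bad, collapse = ", ")))
      }
      raw[[v]] <- coerced
    }
  }
  ts <- as.POSIXct(raw$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M"))
  if (any(is.na(ts))) {
    abort(paste0("unparseable timestamp at data row(s): ",
                 paste(which(is.na(ts)), collapse = ", ")))
  }
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    abort(paste0("duplicate or decreasing timestamps at data row(s): ",
                 paste(which(d <= 0) + 1L, collapse = ", ")))
  }
  raw$timestamp <- ts
  for (v in setdiff(names(raw), "timestamp")) {
    if (is.numeric(raw[[v]])) {
      raw[[v]][raw[[v]] == sentinel] <- NA_real_
    } else {
      raw[[v]][raw[[v]] == as.character(sentinel)] <- NA
    }
  }
  # regularize to a 30-min grid
  grid <- tibble(timestamp = seq(min(ts), max(ts), by = 1800))
  out <- left_join(grid, raw, by = "timestamp")
  as_tibble(out)
}
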