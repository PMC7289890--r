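#' Tidy a fitted light response
#'
#' @param x A [fit_light_response()] object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.light_response <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @rdname tidy.light_response
#' @export
glance.light_response <- function(x, ...) {
  tibble(rmse = x$rmse, n = x$n,
         sigma = summary(x$fit)$sigma,
         converged = TRUE)
}

#' Tidy an annual temperature-sensitivity estimate
#'
#' @param x An [estimate_e0()] object.
#' @param ... Unused.
#' @return For `tidy()`, the per-window fits; for `glance()`, the combined
#'   estimate.
#' @export
tidy.e0_estimate <- function(x, ...) {
  x$windows
}

#' @rdname tidy.e0_estimate
#' @export
glance.e0_estimate <- function(x, ...) {
  tibble(e0 = x$e0, se = x$se,
         n_windows = nrow(x$windows),
         n_accepted = sum(x$windows$accepted))
}

#' Tidy a u* threshold result
#'
#' @param x A [ustar_threshold_mpt()] object.
#' @param ... Unused.
#' @return The per-season threshold tibble.
#' @export
tidy.ustar_result <- function(x, ...) {
  x$thresholds
}

#' @rdname tidy.ustar_result
#' @export
glance.ustar_result <- function(x, ...) {
  tibble(median_threshold = median(x$thresholds$threshold),
         n_seasons = nrow(x$thresholds),
         n_fallback = sum(x$thresholds$fallback),
         in_validity_interval = all(
           x$thresholds$threshold >= x$accepted_range[1] &
             x$thresholds$threshold <= x$accepted_range[2]))
}
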