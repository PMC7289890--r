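#' Convert a CO₂ flux to grams of carbon
#'
#' `flux * dt * 12.011e-6`: a flux in µmol CO₂ m⁻² s⁻¹ sustained over `dt`
#' seconds moves `flux * dt` µmol of carbon, and one µmol of carbon weighs
#' 12.011 µg. The inverse is [gC_to_umol()].
#'
#' @param flux Flux in µmol m⁻² s⁻¹ (vectorised).
#' @param dt Duration in seconds (default one half hour, 1800).
#' @return Mass flux in g C m⁻².
#' @export
#' @examples
#' umol_to_gC(1, 86400)  # one day: ~1.0378 g C m⁻²
umol_to_gC <- function(flux, dt = 1800) {
  if (any(dt <= 0)) abort("`dt` must be > 0")
  flux * dt * 12.011e-6
}

#' @rdname umol_to_gC
#' @param mass Mass flux in g C m⁻².
#' @export
gC_to_umol <- function(mass, dt = 1800) {
  if (any(dt <= 0)) abort("`dt` must be > 0")
  mass / (dt * 12.011e-6)
}

#' Daily, seasonal and annual carbon sums
#'
#' Converts half-hourly fluxes to daily sums in g C m⁻² d⁻¹ (48 half hours
#' per day, end-of-interval timestamps), then aggregates per season and for
#' the whole year: mean daily flux ± sd, cumulative sum, number of days,
#' and a percentile bootstrap confidence interval of the mean daily flux.
#' Incomplete days are excluded from means and prorated (scaled by 48/n)
#' into the sums, with the count reported via a message. The sign
#' convention is preserved throughout: uptake is negative.
#'
#' @param series Gap-filled half-hourly tibble.
#' @param calendar A [season_calendar()].
#' @param vars Flux columns to aggregate (default `nee`, `gpp`, `reco`,
#'   intersected with what is present).
#' @param n_boot Bootstrap resamples for the CI of the mean daily flux
#'   (default 1000; 0 disables).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap (default 1).
#' @return A tibble with one row per season (plus `"annual"`) and variable:
#'   `mean_daily`, `sd_daily`, `ci_lo`, `ci_hi` (g C m⁻² d⁻¹), `sum`
#'   (g C m⁻²), `n_days`. The per-day table is attached as attribute
#'   `daily`. Seasonal sums partition the annual sum exactly.
#' @export
daily_and_seasonal_sums <- function(series, calendar = season_calendar(),
                                    vars = c("nee", "gpp", "reco"),
                                    n_boot = 1000, level = 0.95, seed = 1L) {
  assert_half_hourly(series, "timestamp")
  vars <- intersect(vars, names(series))
  if (length(vars) == 0) abort("none of `vars` present in `series`")
  if (any(!is.finite(series$nee))) {
    abort("`series` must be gap-filled (no missing NEE) before aggregation")
  }
  date <- as.Date(series$timestamp - lubridate::dminutes(15),
                  tz = attr_tz(series$timestamp))
  daily <- series %>%
    mutate(date = date) %>%
    select("date", dplyr::all_of(vars)) %>%
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") %>%
    group_by(.data$date, .data$variable) %>%
    summarise(n_hh = sum(is.finite(.data$value)),
              sum_gC = umol_to_gC(sum(.data$value[is.finite(.data$value)]),
                                  1800),
              .groups = "drop") %>%
    mutate(complete = .data$n_hh == 48L,
           sum_gC = if_else(.data$n_hh > 0,
                            .data$sum_gC * 48 / .data$n_hh, NA_real_),
           season = assign_season(.data$date, calendar))
  n_incomplete <- daily %>% filter(!.data$complete) %>% nrow()
  if (n_incomplete > 0) {
    inform(sprintf("%d day-variable sums prorated from incomplete days",
                   n_incomplete))
  }

  summarise_block <- function(d, label) {
    d %>%
      group_by(.data$variable) %>%
      summarise(
        mean_daily = mean(.data$sum_gC[.data$complete]),
        sd_daily = sd(.data$sum_gC[.data$complete]),
        ci_lo = if (n_boot > 0)
          bootstrap_ci(.data$sum_gC[.data$complete], n_boot = n_boot,
                       level = level, seed = seed)$lo else NA_real_,
        ci_hi = if (n_boot > 0)
          bootstrap_ci(.data$sum_gC[.data$complete], n_boot = n_boot,
                       level = level, seed = seed)$hi else NA_real_,
        sum = sum(.data$sum_gC, na.rm = TRUE),
        n_days = n(),
        .groups = "drop") %>%
      mutate(season = label, .before = 1)
  }
  seasonal <- daily %>%
    group_by(.data$season) %>%
    dplyr::group_map(~ summarise_block(.x, .y$season)) %>%
    bind_rows()
  annual <- summarise_block(daily, "annual")
  out <- bind_rows(seasonal, annual)
  attr(out, "daily") <- daily
  out
}

#' Ecosystem carbon-use efficiency (NEP/GPP)
#'
#' Net ecosystem production is the negative of NEE; carbon-use efficiency
#' is NEP divided by gross primary production, both taken from cumulative
#' sums in the signed convention (uptake negative):
#' `(-nee_sum) / (-gpp_sum)`. Reported rounded to 2 decimals by default.
#'
#' @param nee_sum Cumulative NEE (g C m⁻², negative for a sink).
#' @param gpp_sum Cumulative GPP (g C m⁻², negative in the signed
#'   convention); must be nonzero.
#' @param digits Rounding of the reported ratio (default 2; `Inf` for
#'   unrounded).
#' @return The NEP/GPP ratio.
#' @export
#' @examples
#' carbon_use_efficiency(-169.0, -414.7)  # 0.41
carbon_use_efficiency <- function(nee_sum, gpp_sum, digits = 2) {
  if (any(gpp_sum == 0)) abort("GPP sum is zero: NEP/GPP undefined")
  ratio <- (-nee_sum) / (-gpp_sum)
  if (is.finite(digits)) round(ratio, digits) else ratio
}

#' Seasonal means over a fixed clock window
#'
#' Mean ± sd of a variable over all records whose clock time falls in a
#' half-hour-aligned window (e.g. 10:00-12:00 for midday, 22:00-00:00 for
#' nighttime), grouped by season and annually. With the end-of-interval
#' timestamp convention a record stamped 10:30 covers 10:00-10:30, so the
#' 10:00-12:00 window collects the stamps 10:30, 11:00, 11:30 and 12:00.
#'
#' @param series Half-hourly tibble.
#' @param start,end Window bounds as `"HH:MM"`; `end` may be `"00:00"`
#'   (midnight) or before `start` to wrap the day boundary.
#' @param var Variable to average (default `"nee"`).
#' @param calendar A [season_calendar()].
#' @return Tibble with `season` (incl. `"annual"`), `mean`, `sd`, `n`.
#' @export
window_mean <- function(series, start = "10:00", end = "12:00",
                        var = "nee", calendar = season_calendar()) {
  assert_half_hourly(series, c("timestamp", var))
  s <- parse_clock(start)
  e <- parse_clock(end)
  if (e == 0) e <- 24
  if (e == s) abort("empty clock window")
  clock <- clock_hour(series$timestamp)
  clock[clock == 0] <- 24
  inw <- if (e > s) clock > s & clock <= e else clock > s | clock <= e
  if (!any(inw)) abort("empty clock window")
  dat <- tibble(
    season = assign_season(series$timestamp[inw], calendar),
    value = series[[var]][inw]
  )
  per_season <- dat %>%
    group_by(.data$season) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n = sum(is.finite(.data$value)), .groups = "drop")
  annual <- dat %>%
    summarise(season = "annual", mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n = sum(is.finite(.data$value)))
  bind_rows(per_season, annual)
}

parse_clock <- function(x) {
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  parts[1] + parts[2] / 60
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' percentile interval of the resample means. Reproducible under `seed`.
#' Significance of a seasonal difference is conventionally judged by the
#' degree of overlap of two such intervals.
#'
#' @param x Numeric values (daily sums or means); needs at least 3 finite
#'   values for a CI, otherwise the mean is returned with an undefined
#'   (NA) interval and `flagged = TRUE`.
#' @param n_boot Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (default 1).
#' @return A one-row tibble: `mean`, `lo`, `hi`, `n`, `flagged`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000, level = 0.95, seed = 1L) {
  x <- x[is.finite(x)]
  m <- mean(x)
  if (length(x) < 3) {
    return(tibble(mean = m, lo = NA_real_, hi = NA_real_,
                  n = length(x), flagged = TRUE))
  }
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(b) mean(sample(x, length(x), replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE)
  tibble(mean = m, lo = qs[1], hi = qs[2], n = length(x), flagged = FALSE)
}

#' Pearson correlation matrix of fluxes and drivers
#'
#' Pairwise Pearson correlations (with two-sided p-values) among flux
#' components and meteorological variables, per season. Pairs are computed
#' on pairwise-complete observations; variables with zero variance give an
#' undefined correlation and are flagged.
#'
#' @param series Tibble of records (half-hourly or daily means).
#' @param vars Variables to correlate (intersected with the columns
#'   present; default NEE, GPP, Reco and the drivers).
#' @param calendar A [season_calendar()]; `by_season = FALSE` gives one
#'   overall matrix labelled `"all"`.
#' @param by_season Group by season (default TRUE).
#' @param min_n Minimum pairwise-complete observations (default 10).
#' @return Long tibble: `season`, `var1`, `var2`, `r`, `p`, `n`,
#'   `sig_05`, `sig_01`, `flagged` (zero variance or n < `min_n`).
#'   Includes the unit diagonal; symmetric in `var1`/`var2`.
#' @export
correlation_matrix <- function(series,
                               vars = c("nee", "gpp", "reco", "ta", "ts",
                                        "vpd", "rh", "rg"),
                               calendar = season_calendar(),
                               by_season = TRUE, min_n = 10) {
  vars <- intersect(vars, names(series))
  if (length(vars) < 2) abort("need at least two variables to correlate")
  season <- if (by_season) {
    assert_half_hourly(series, "timestamp")
    assign_season(series$timestamp, calendar)
  } else {
    rep("all", nrow(series))
  }
  grid <- tidyr::expand_grid(var1 = vars, var2 = vars)
  purrr::map(unique(season), function(ssn) {
    d <- series[season == ssn, vars, drop = FALSE]
    purrr::pmap(grid, function(var1, var2) {
      x <- d[[var1]]; y <- d[[var2]]
      ok <- is.finite(x) & is.finite(y)
      nn <- sum(ok)
      if (nn < min_n || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        return(tibble(season = ssn, var1 = var1, var2 = var2,
                      r = NA_real_, p = NA_real_, n = nn,
                      sig_05 = NA, sig_01 = NA, flagged = TRUE))
      }
      if (var1 == var2) {
        return(tibble(season = ssn, var1 = var1, var2 = var2,
                      r = 1, p = 0, n = nn,
                      sig_05 = TRUE, sig_01 = TRUE, flagged = FALSE))
      }
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      tibble(season = ssn, var1 = var1, var2 = var2,
             r = unname(ct$estimate), p = ct$p.value, n = nn,
             sig_05 = ct$p.value < 0.05, sig_01 = ct$p.value < 0.01,
             flagged = FALSE)
    }) %>% bind_rows()
  }) %>% bind_rows()
}
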