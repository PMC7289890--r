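#' Site configuration for the synthetic flux-tower year
#'
#' Describes the statistical structure of a semiarid, seasonally dry
#' tropical forest site: a single wet season, low annual rainfall, a
#' rainfall-driven vegetation-state index (EVI-like, dimensionless), and
#' strong diurnal cycles of radiation and temperature. Defaults emulate a
#' Caatinga tower year (wet season mid January to end of May, 513 mm of
#' rain, vegetation index spanning 0.16-0.42).
#'
#' @param latitude Site latitude in decimal degrees (south negative).
#' @param year Calendar year to simulate.
#' @param wet_season Character vector `c(start, end)` as `"mm-dd"`.
#' @param annual_rain_target Annual rainfall total in mm (> 0). Event
#'   amounts are scaled so the annual sum equals this target exactly.
#' @param veg_index_range Range `c(min, max)` of the vegetation-state
#'   index; both in (0, 1), min < max.
#' @param veg_lag_days Time constant (days) of the first-order filter that
#'   turns antecedent rainfall into vegetation state.
#' @param ta_mean Annual mean air temperature (°C).
#' @param ta_diurnal_amp,ta_seasonal_amp Diurnal and seasonal air
#'   temperature amplitudes (°C). Zero amplitudes give a constant
#'   seasonal/diurnal component.
#' @param clearness Mean daily atmospheric transmissivity applied to the
#'   top-of-atmosphere solar flux (0-1).
#' @param clearness_sd Day-to-day standard deviation of the transmissivity
#'   (0 gives radiation that follows pure solar geometry on rain-free days).
#' @param ta_noise_sd Day-scale temperature noise (°C); 0 together with zero
#'   amplitudes gives a constant air temperature.
#' @param noise_sd_nee Standard deviation of the Gaussian measurement noise
#'   added to NEE (µmol m⁻² s⁻¹).
#' @param ustar_median Median friction velocity (m s⁻¹) of the lognormal
#'   u* model.
#' @param ustar_suppression_threshold Friction velocity (m s⁻¹) below which
#'   the *observed* nighttime NEE is proportionally underestimated,
#'   emulating flux loss under low turbulence (the defect the moving point
#'   test detects). 0 disables the suppression; the biophysical truth is
#'   never affected.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `site_config`.
#' @export
site_config <- function(latitude = -6.58, year = 2014,
                        wet_season = c("01-15", "05-31"),
                        annual_rain_target = 513,
                        veg_index_range = c(0.16, 0.42),
                        veg_lag_days = 30,
                        ta_mean = 28.9, ta_diurnal_amp = 5,
                        ta_seasonal_amp = 1.8,
                        clearness = 0.65,
                        clearness_sd = 0.06,
                        ta_noise_sd = 0.6,
                        noise_sd_nee = 1,
                        ustar_median = 0.3,
                        ustar_suppression_threshold = 0.25,
                        seed = 1L) {
  if (days_in_year(year) <= 0) abort("non-positive year length")
  if (length(wet_season) != 2 || any(!grepl("^\\d{2}-\\d{2}$", wet_season))) {
    abort("`wet_season` must be c('mm-dd', 'mm-dd')")
  }
  if (annual_rain_target <= 0) abort("`annual_rain_target` must be > 0")
  if (length(veg_index_range) != 2 ||
      veg_index_range[1] >= veg_index_range[2] ||
      any(veg_index_range <= 0) || any(veg_index_range >= 1)) {
    abort("`veg_index_range` must satisfy 0 < min < max < 1")
  }
  if (noise_sd_nee < 0) abort("`noise_sd_nee` must be >= 0")
  structure(list(latitude = latitude, year = year, wet_season = wet_season,
                 annual_rain_target = annual_rain_target,
                 veg_index_range = veg_index_range,
                 veg_lag_days = veg_lag_days,
                 ta_mean = ta_mean, ta_diurnal_amp = ta_diurnal_amp,
                 ta_seasonal_amp = ta_seasonal_amp, clearness = clearness,
                 clearness_sd = clearness_sd, ta_noise_sd = ta_noise_sd,
                 noise_sd_nee = noise_sd_nee, ustar_median = ustar_median,
                 ustar_suppression_threshold = ustar_suppression_threshold,
                 seed = as.integer(seed)),
            class = "site_config")
}

# run code with a local RNG state so generators are reproducible without
# disturbing the caller's random stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# sine of solar elevation at a given latitude for a vector of times
sin_solar_elevation <- function(timestamp, latitude) {
  doy <- lubridate::yday(timestamp)
  hour <- clock_hour(timestamp)
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  hang <- pi / 12 * (hour - 12)
  lat <- latitude * pi / 180
  sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hang)
}

#' Simulate one year of half-hourly site meteorology
#'
#' Generates a complete half-hourly meteorological year: global radiation
#' from solar geometry at the site latitude with day-scale cloudiness,
#' diurnal/seasonal air and soil temperature cycles, relative humidity,
#' vapour pressure deficit from a Magnus-type saturation formula
#' (`es = 0.61094 * exp(17.625 ta / (ta + 243.04))` kPa), rainfall
#' concentrated in the wet season and scaled to the annual target, a
#' vegetation-state index as a first-order filter of antecedent rainfall
#' rescaled to the configured range, friction velocity and pressure.
#'
#' @param config A [site_config()].
#' @return A tibble of 17,520 (17,568 in leap years) half-hourly records
#'   with columns `timestamp`, `nee` (all missing; fluxes come from
#'   [simulate_true_fluxes()]), `rg`, `ta`, `ts`, `rh`, `vpd`, `precip`,
#'   `ustar`, `pa`, `veg_index`.
#' @export
#' @examples
#' met <- simulate_met_year(site_config(seed = 7))
#' range(met$veg_index)
simulate_met_year <- function(config) {
  stopifnot(inherits(config, "site_config"))
  with_seed(config$seed, {
    ts_grid <- hh_grid(config$year)
    n <- length(ts_grid)
    doy <- lubridate::yday(ts_grid - lubridate::dminutes(15))
    hour <- clock_hour(ts_grid - lubridate::dminutes(15))
    n_days <- days_in_year(config$year)
    day_of <- rep(seq_len(n_days), each = 48L)[seq_len(n)]

    # --- rainfall: wet-season clustered events, scaled to the annual target
    dates <- as.Date(ts_grid[seq(1, n, by = 48L)] - lubridate::dhours(12))
    md <- format(dates, "%m-%d")
    in_wet <- md_in_interval(md, config$wet_season[1], config$wet_season[2])
    p_rain <- ifelse(in_wet, 0.35, 0.04)
    rain_day <- rbinom(n_days, 1, p_rain) == 1
    day_amount <- numeric(n_days)
    day_amount[rain_day] <- rgamma(sum(rain_day), shape = 0.7, scale = 12)
    if (sum(day_amount) > 0) {
      day_amount <- day_amount * config$annual_rain_target / sum(day_amount)
    }
    precip <- numeric(n)
    for (d in which(day_amount > 0)) {
      slots <- (d - 1L) * 48L + sample(26:42, sample(1:4, 1))
      w <- runif(length(slots))
      precip[slots] <- precip[slots] + day_amount[d] * w / sum(w)
    }

    # --- vegetation state: first-order filter of daily rain, rescaled
    daily_rain <- vapply(seq_len(n_days), function(d) {
      sum(precip[((d - 1L) * 48L + 1L):(d * 48L)])
    }, numeric(1))
    v <- numeric(n_days)
    v[1] <- mean(daily_rain)
    for (d in 2:n_days) {
      v[d] <- v[d - 1] + (daily_rain[d] - v[d - 1]) / config$veg_lag_days
    }
    rng <- range(v)
    vr <- config$veg_index_range
    veg_daily <- if (diff(rng) > 0) {
      pmin(pmax(vr[1] + (v - rng[1]) / diff(rng) * diff(vr), vr[1]), vr[2])
    } else {
      rep(mean(vr), n_days)
    }
    veg_index <- veg_daily[day_of]

    # --- radiation: solar geometry times day-scale clearness
    sin_el <- pmax(sin_solar_elevation(ts_grid - lubridate::dminutes(15),
                                       config$latitude), 0)
    clear_day <- pmin(pmax(
      config$clearness + rnorm(n_days, 0, config$clearness_sd) -
        0.35 * (daily_rain > 1), 0.15), 1)
    rg <- 1367 * sin_el * clear_day[day_of]

    # --- temperature: seasonal + diurnal + small day-scale noise
    ta_seas <- config$ta_mean +
      config$ta_seasonal_amp * cos(2 * pi * (doy - 330) / 365)
    ta_day_noise <- rnorm(n_days, 0, config$ta_noise_sd)[day_of]
    ta <- ta_seas - config$ta_diurnal_amp * cos(2 * pi * (hour - 14) / 24) +
      ta_day_noise
    ts_soil <- ta_seas + 2.5 -
      (config$ta_diurnal_amp + 1.2) * cos(2 * pi * (hour - 15) / 24) +
      ta_day_noise

    # --- humidity & VPD (Magnus saturation vapour pressure, kPa)
    wetness <- (veg_index - vr[1]) / max(diff(vr), 1e-9)
    rh <- 52 + 22 * wetness + 12 * cos(2 * pi * (hour - 5) / 24) +
      rnorm(n_days, 0, 3)[day_of]
    rh <- pmin(pmax(rh, 5), 100)
    es <- 0.61094 * exp(17.625 * ta / (ta + 243.04))
    vpd <- pmax(es * (1 - rh / 100), 0)

    # --- friction velocity: lognormal, higher by day
    is_day <- rg > 10
    ustar <- exp(rnorm(n, log(config$ustar_median), 0.35)) *
      ifelse(is_day, 1.25, 0.85)

    pa <- 98900 + rnorm(n, 0, 80)

    tibble(timestamp = ts_grid, nee = NA_real_, rg = rg, ta = ta,
           ts = ts_soil, rh = rh, vpd = vpd, precip = precip,
           ustar = ustar, pa = pa, veg_index = veg_index)
  })
}

#' Generate ground-truth fluxes on top of simulated meteorology
#'
#' Respiration follows the Lloyd-Taylor temperature response scaled by the
#' vegetation-state index (normalised to unit mean); gross uptake follows
#' the rectangular hyperbola of global radiation scaled by the same index
#' raised to `gpp_veg_exp` (leaf area drives photosynthesis more strongly
#' than it drives respiration) and is zero whenever `rg` is zero. Observed
#' NEE is `reco - gpp` plus optional homoscedastic Gaussian noise; under
#' low nighttime turbulence (u* below the configured suppression
#' threshold) the observed NEE is additionally scaled by
#' `ustar / threshold`, emulating the flux loss that the moving point test
#' is designed to detect. The `truth` table always carries the unsuppressed
#' biophysical fluxes.
#'
#' @param met Complete meteorological year from [simulate_met_year()]
#'   (no gaps in `rg`, `ta`, `veg_index`).
#' @param lt [lt_params()] generating respiration.
#' @param lr [lr_params()] generating the light response (`gamma` unused:
#'   respiration comes from `lt`).
#' @param config The [site_config()] (supplies `noise_sd_nee` and the seed).
#' @param gpp_veg_exp Exponent of the normalised vegetation index in the
#'   GPP scaling (default 2, giving site-like wet/dry seasonal contrast).
#' @return A list of class `truth_bundle`: `series` (met with observed
#'   `nee`), `truth` (tibble of `timestamp`, `true_gpp`, `true_reco`,
#'   `true_nee`) and `params`.
#' @export
simulate_true_fluxes <- function(met, lt = lt_params(), lr = lr_params(),
                                 config = site_config(), gpp_veg_exp = 2) {
  assert_half_hourly(met, c("timestamp", "rg", "ta", "veg_index"))
  if (any(!is.finite(met$rg)) || any(!is.finite(met$ta))) {
    abort("`met` must be gap-free; fluxes are generated from complete drivers")
  }
  scale <- met$veg_index / mean(met$veg_index)
  true_reco <- lloyd_taylor(met$ta, lt) * scale
  hyp <- ifelse(met$rg > 0,
                lr$alpha * lr$beta * met$rg / (lr$alpha * met$rg + lr$beta),
                0)
  true_gpp <- pmax(-hyp * scale^gpp_veg_exp, 0)
  true_nee <- true_reco - true_gpp
  supp <- ustar_suppression_factor(met, config)
  nee_obs <- if (config$noise_sd_nee > 0) {
    with_seed(config$seed + 1000L,
              true_nee * supp + rnorm(length(true_nee),
                                      0, config$noise_sd_nee))
  } else {
    true_nee * supp
  }
  series <- met
  series$nee <- nee_obs
  structure(list(series = series,
                 truth = tibble(timestamp = met$timestamp,
                                true_gpp = true_gpp,
                                true_reco = true_reco,
                                true_nee = true_nee),
                 params = list(lt = lt, lr = lr, config = config)),
            class = "truth_bundle")
}

# multiplicative observation factor for low-turbulence nights: linear ramp
# in u* below the threshold, 1 by day and above the threshold
ustar_suppression_factor <- function(met, config, rg_threshold = 10) {
  thr <- config$ustar_suppression_threshold
  if (is.null(thr) || thr <= 0) return(rep(1, nrow(met)))
  night <- is.finite(met$rg) & met$rg < rg_threshold
  ifelse(night & is.finite(met$ustar) & met$ustar < thr,
         pmax(met$ustar, 0) / thr, 1)
}

#' Degradation settings for synthetic series
#'
#' @param gap_fraction Fraction of NEE records to blank out, in `[0, 1)`.
#' @param block_gap_lengths Lengths (half hours) of contiguous gap blocks
#'   to plant before random singleton gaps.
#' @param spike_count Number of spikes to inject.
#' @param spike_magnitude Spike size in multiples of the scaled MAD of NEE
#'   (> 0).
#' @param calm_night_fraction Fraction of nights turned into calm
#'   (low-turbulence) nights.
#' @param calm_ustar_max Calm-night friction velocities are drawn uniformly
#'   below this value (m s⁻¹).
#' @param seed Integer seed.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(gap_fraction = 0.1,
                             block_gap_lengths = c(4L, 12L, 48L),
                             spike_count = 20L, spike_magnitude = 10,
                             calm_night_fraction = 0.2,
                             calm_ustar_max = 0.18,
                             seed = 1L) {
  if (gap_fraction < 0 || gap_fraction >= 1) {
    abort("`gap_fraction` must be in [0, 1)")
  }
  if (calm_night_fraction < 0 || calm_night_fraction >= 1) {
    abort("`calm_night_fraction` must be in [0, 1)")
  }
  if (spike_magnitude <= 0) abort("`spike_magnitude` must be > 0")
  structure(list(gap_fraction = gap_fraction,
                 block_gap_lengths = as.integer(block_gap_lengths),
                 spike_count = as.integer(spike_count),
                 spike_magnitude = spike_magnitude,
                 calm_night_fraction = calm_night_fraction,
                 calm_ustar_max = calm_ustar_max,
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Degrade a synthetic series with gaps, spikes and calm nights
#'
#' Emulates the defects that quality control must remove: missing NEE
#' (random singletons plus contiguous blocks), spikes displaced from the
#' local median by at least `spike_magnitude` scaled MADs, and calm nights
#' whose friction velocity is redrawn below `calm_ustar_max` with the
#' nighttime flux suppressed proportionally (the physical signature of
#' low-turbulence flux loss). Every injected defect is recorded in a
#' ledger so tests can verify recovery.
#'
#' @param x A `truth_bundle` from [simulate_true_fluxes()] (preferred: calm
#'   nights are then re-suppressed consistently with the generator's
#'   low-turbulence observation model) or a plain half-hourly tibble with
#'   observed `nee` (calm-night NEE is then scaled proportionally to the
#'   redrawn u*).
#' @param spec A [degradation_spec()].
#' @param rg_threshold Nighttime definition for calm-night planting
#'   (W m⁻²).
#' @return A list of class `degraded_series`: `series` (degraded tibble)
#'   and `ledger` (tibble with `index`, `timestamp`, `type` in
#'   `gap`/`spike`/`calm`, `original`, `injected`).
#' @export
degrade_series <- function(x, spec = degradation_spec(),
                           rg_threshold = 10) {
  truth <- NULL
  config <- NULL
  if (inherits(x, "truth_bundle")) {
    series <- x$series
    truth <- x$truth
    config <- x$params$config
  } else {
    series <- x
  }
  assert_half_hourly(series, c("timestamp", "nee", "rg", "ustar"))
  stopifnot(inherits(spec, "degradation_spec"))
  n <- nrow(series)
  out <- series
  with_seed(spec$seed, {
    ledger <- list()

    # --- gaps: blocks first, then singletons up to the budget
    n_gap <- round(spec$gap_fraction * n)
    gap_idx <- integer(0)
    if (n_gap > 0) {
      for (len in spec$block_gap_lengths) {
        if (length(gap_idx) + len > n_gap) break
        start <- sample.int(n - len + 1L, 1L)
        gap_idx <- union(gap_idx, start:(start + len - 1L))
      }
      remaining <- n_gap - length(gap_idx)
      if (remaining > 0) {
        pool <- setdiff(seq_len(n), gap_idx)
        gap_idx <- c(gap_idx, sample(pool, remaining))
      }
      gap_idx <- sort(gap_idx)
      night <- is.finite(series$rg) & series$rg < rg_threshold
      if (all(which(night & is.finite(series$nee)) %in% gap_idx)) {
        abort("`gap_fraction` leaves no valid nighttime data; refuse")
      }
      ledger$gap <- tibble(index = gap_idx,
                           timestamp = series$timestamp[gap_idx],
                           type = "gap",
                           original = series$nee[gap_idx],
                           injected = NA_real_)
      out$nee[gap_idx] <- NA_real_
    }

    # --- spikes: displaced from the running median by >= magnitude MADs
    if (spec$spike_count > 0) {
      pool <- setdiff(which(is.finite(out$nee)), gap_idx)
      sp_idx <- sort(sample(pool, spec$spike_count))
      mad_nee <- mad(series$nee, na.rm = TRUE)  # 1.4826-scaled by default
      loc_med <- vapply(sp_idx, function(i) {
        w <- max(1L, i - 24L):min(n, i + 24L)
        median(series$nee[w], na.rm = TRUE)
      }, numeric(1))
      sgn <- sample(c(-1, 1), spec$spike_count, replace = TRUE)
      injected <- loc_med + sgn * 1.5 * spec$spike_magnitude * mad_nee
      ledger$spike <- tibble(index = sp_idx,
                             timestamp = series$timestamp[sp_idx],
                             type = "spike",
                             original = series$nee[sp_idx],
                             injected = injected)
      out$nee[sp_idx] <- injected
    }

    # --- calm nights: redraw u* low, suppress the flux proportionally
    if (spec$calm_night_fraction > 0) {
      night <- is.finite(series$rg) & series$rg < rg_threshold
      night_date <- as.Date(series$timestamp - lubridate::dhours(12))
      nights <- unique(night_date[night])
      calm_nights <- sample(nights,
                            floor(spec$calm_night_fraction * length(nights)))
      calm_idx <- which(night & night_date %in% calm_nights)
      if (length(calm_idx) > 0) {
        new_ustar <- runif(length(calm_idx), 0.02, spec$calm_ustar_max)
        ledger$calm <- tibble(index = calm_idx,
                              timestamp = series$timestamp[calm_idx],
                              type = "calm",
                              original = series$ustar[calm_idx],
                              injected = new_ustar)
        # only records still carrying an (unspiked) observation get a new
        # flux value; gaps stay gaps and spikes keep their ledger value
        untouched <- is.finite(out$nee[calm_idx]) &
          out$nee[calm_idx] == series$nee[calm_idx]
        if (!is.null(truth) && !is.null(config) &&
            config$ustar_suppression_threshold > 0) {
          # re-apply the generator's low-turbulence observation model at the
          # new u*, keeping the original measurement-noise residual
          thr <- config$ustar_suppression_threshold
          old_supp <- pmin(series$ustar[calm_idx], thr) / thr
          new_supp <- pmin(new_ustar, thr) / thr
          resid <- series$nee[calm_idx] -
            truth$true_nee[calm_idx] * old_supp
          upd <- truth$true_nee[calm_idx] * new_supp + resid
        } else {
          upd <- out$nee[calm_idx] * new_ustar / spec$calm_ustar_max
        }
        out$nee[calm_idx[untouched]] <- upd[untouched]
        out$ustar[calm_idx] <- new_ustar
      }
    }

    structure(list(series = out, ledger = bind_rows(ledger)),
              class = "degraded_series")
  })
}

#' Simulate a 10 Hz high-frequency averaging block
#'
#' Draws vertical wind and CO₂ concentration samples from a bivariate model
#' whose population covariance times the air density equals the target
#' turbulent flux, plus streamwise and lateral wind components for rotation
#' tests. The empirical covariance flux converges to the target as `n`
#' grows.
#'
#' @param target_flux Target turbulent CO₂ flux (µmol m⁻² s⁻¹).
#' @param rho_air Molar air density (mol m⁻³).
#' @param n Number of samples (≥ 2); 18,000 is one half hour at 10 Hz.
#' @param seed Integer seed.
#' @param mean_wind Mean streamwise wind (m s⁻¹).
#' @param sd_w Standard deviation of vertical wind (m s⁻¹).
#' @param start_time Block start time.
#' @return An [hf_block()].
#' @export
simulate_high_frequency_block <- function(target_flux, rho_air = 40,
                                          n = 18000, seed = 1L,
                                          mean_wind = 2, sd_w = 0.3,
                                          start_time = as.POSIXct(
                                            "2014-01-01 12:00:00", tz = "UTC")) {
  if (n < 2) abort("`n` must be >= 2")
  with_seed(seed, {
    w <- rnorm(n, 0, sd_w)
    slope <- (target_flux / rho_air) / sd_w^2
    c_ <- 400 + slope * w + rnorm(n, 0, 5)
    u <- mean_wind + rnorm(n, 0, 0.5)
    v <- rnorm(n, 0, 0.5)
    hf_block(u = u, v = v, w = w, c = c_, rho_air = rho_air,
             sampling_rate = 10, start_time = start_time)
  })
}
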