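#' Lloyd-Taylor respiration parameters
#'
#' Container for the exponential temperature-response model of ecosystem
#' respiration used for nighttime-based flux partitioning:
#' \deqn{R_{eco} = R_{eco,ref} \exp\left(E_0 \left(\frac{1}{T_{ref}-T_0} -
#'   \frac{1}{T_a-T_0}\right)\right)}
#' All temperatures are handled in degrees Celsius.
#'
#' @param reco_ref Respiration rate at the reference temperature
#'   (µmol m⁻² s⁻¹), must be > 0.
#' @param e0 Temperature sensitivity (K), must be > 0 for an increasing
#'   response.
#' @param t_ref Reference temperature (°C), default 15.
#' @param t0 Baseline temperature (°C), default −42.02; must be below `t_ref`.
#' @return An object of class `lt_params`.
#' @export
#' @examples
#' lloyd_taylor(25, lt_params(reco_ref = 2, e0 = 150))
lt_params <- function(reco_ref = 1.4, e0 = 150, t_ref = 15, t0 = -42.02) {
  if (reco_ref <= 0) abort("`reco_ref` must be positive.")
  if (e0 < 0) abort("`e0` must be non-negative.")
  if (t0 >= t_ref) abort("`t0` must be below `t_ref`.")
  structure(list(reco_ref = reco_ref, e0 = e0, t_ref = t_ref, t0 = t0),
            class = "lt_params")
}

#' Rectangular-hyperbola light-response parameters
#'
#' Parameters of the light-response model of daytime net ecosystem exchange,
#' \deqn{NEE = \frac{\alpha \beta R_g}{\alpha R_g + \beta} + \gamma,}
#' with `alpha` the initial slope (light-use efficiency, µmol C J⁻¹),
#' `beta` the CO₂ uptake at light saturation (µmol C m⁻² s⁻¹) and `gamma`
#' a respiration offset (µmol C m⁻² s⁻¹). Under the micrometeorological
#' sign convention (uptake negative) `alpha` and `beta` are negative.
#'
#' @param alpha Initial slope (µmol C J⁻¹).
#' @param beta Saturation uptake (µmol C m⁻² s⁻¹); |beta| must be < 100.
#' @param gamma Respiration offset (µmol C m⁻² s⁻¹).
#' @param rmse,n Optional fit diagnostics.
#' @return An object of class `lr_params`.
#' @export
lr_params <- function(alpha = -0.015, beta = -25, gamma = 2,
                      rmse = NA_real_, n = NA_integer_) {
  if (!all(is.finite(c(alpha, beta, gamma)))) {
    abort("light-response parameters must be finite")
  }
  if (abs(beta) >= 100) abort("|beta| must be < 100 µmol m⁻² s⁻¹.")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 rmse = rmse, n = n),
            class = "lr_params")
}

#' Evaluate the Lloyd-Taylor respiration model
#'
#' @param ta Air temperature in °C. Values above 150 are rejected as
#'   Kelvin-scale inputs; values at or below `p$t0` are a domain error.
#' @param p An [lt_params()] object.
#' @return Respiration in µmol m⁻² s⁻¹ (strictly positive, strictly
#'   increasing in `ta` when `e0 > 0`).
#' @export
lloyd_taylor <- function(ta, p) {
  stopifnot(inherits(p, "lt_params"))
  finite <- is.finite(ta)
  if (any(ta[finite] > 150)) {
    abort("`ta` looks Kelvin-scaled (> 150); temperatures must be in °C.")
  }
  if (any(ta[finite] <= p$t0)) {
    abort(sprintf("`ta` must exceed t0 = %.2f °C.", p$t0))
  }
  p$reco_ref * exp(p$e0 * (1 / (p$t_ref - p$t0) - 1 / (ta - p$t0)))
}

# the Lloyd-Taylor temperature shape with unit reco_ref
lt_shape <- function(ta, e0, t_ref, t0) {
  exp(e0 * (1 / (t_ref - t0) - 1 / (ta - t0)))
}

#' Estimate the temperature sensitivity E0 from nighttime fluxes
#'
#' Fits the Lloyd-Taylor model to valid nighttime NEE (= respiration) in
#' sliding windows, keeps estimates inside an acceptance range, and combines
#' them into one annual value by an uncertainty-weighted mean.
#'
#' @param series Half-hourly tibble with `timestamp`, `nee`, `ta`.
#' @param night Logical nighttime mask (see [flag_nighttime()]).
#' @param period_days Window length in days (default 15).
#' @param shift_days Step between window starts (default 5).
#' @param accept Acceptance interval for E0 in K (default `c(30, 450)`).
#' @param min_n Minimum valid records per window (default 6).
#' @param min_ta_range Minimum air-temperature span per window in °C
#'   (default 5); isothermal windows are unidentifiable and rejected.
#' @param t_ref,t0 Fixed model constants (°C).
#' @return An object of class `e0_estimate`: list with `e0`, `se`, and a
#'   `windows` tibble of per-window fits. Errors if no window is accepted.
#' @export
estimate_e0 <- function(series, night, period_days = 15, shift_days = 5,
                        accept = c(30, 450), min_n = 6, min_ta_range = 5,
                        t_ref = 15, t0 = -42.02) {
  assert_half_hourly(series, c("timestamp", "nee", "ta"))
  ok <- night & is.finite(series$nee) & is.finite(series$ta)
  nt <- series[which(ok), c("timestamp", "nee", "ta")]
  if (nrow(nt) < min_n) abort("not enough valid nighttime records to fit E0")

  t_start <- min(series$timestamp)
  day_idx <- as.numeric(difftime(nt$timestamp, t_start, units = "days"))
  n_days <- ceiling(max(day_idx))
  starts <- seq(0, max(0, n_days - period_days), by = shift_days)

  fits <- purrr::map(starts, function(s) {
    inw <- day_idx >= s & day_idx < s + period_days
    dat <- nt[inw, ]
    if (nrow(dat) < min_n) return(NULL)
    if (diff(range(dat$ta)) < min_ta_range) return(NULL)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        nee ~ rref * lt_shape(ta, e0, t_ref, t0),
        data = dat,
        start = list(rref = max(mean(dat$nee), 0.1), e0 = 100),
        lower = c(rref = 1e-6, e0 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    est <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit)))[["e0"]], error = function(e) NA_real_)
    tibble(start_day = s, n = nrow(dat),
           ta_range = diff(range(dat$ta)),
           e0 = est[["e0"]], e0_se = se, rref = est[["rref"]])
  })
  windows <- bind_rows(fits)
  if (nrow(windows) == 0) {
    abort(paste("no window yielded an E0 fit; use a fixed E0",
                "(e.g. lt_params()) instead"))
  }
  windows$accepted <- is.finite(windows$e0) &
    windows$e0 >= accept[1] & windows$e0 <= accept[2] &
    is.finite(windows$e0_se) & windows$e0_se > 0
  acc <- windows[windows$accepted, ]
  if (nrow(acc) == 0) {
    abort(paste("no E0 estimate inside the acceptance range",
                sprintf("[%g, %g] K; fall back to a fixed E0.", accept[1], accept[2])))
  }
  w <- 1 / acc$e0_se^2
  e0_hat <- sum(w * acc$e0) / sum(w)
  structure(list(e0 = e0_hat, se = sqrt(1 / sum(w)), windows = windows,
                 t_ref = t_ref, t0 = t0),
            class = "e0_estimate")
}

#' Short-window reference respiration trajectory
#'
#' With the temperature sensitivity fixed, the reference respiration
#' `reco_ref` is re-estimated in short consecutive windows as the
#' least-squares scale of the Lloyd-Taylor temperature shape against valid
#' nighttime NEE, then interpolated linearly to every half hour. This lets
#' the respiration base level track seasonal changes (moisture, vegetation
#' state) that the temperature response alone cannot express.
#'
#' @inheritParams estimate_e0
#' @param e0 Fixed temperature sensitivity (K), typically from
#'   [estimate_e0()] (either the object or a number).
#' @param window_days Window length in days (default 4).
#' @param rref_floor Lower bound applied to the trajectory (µmol m⁻² s⁻¹).
#' @return Tibble with one row per half hour: `timestamp`, `reco_ref`.
#'   Windows without nights are bridged by interpolation.
#' @export
estimate_reco_ref <- function(series, night, e0, window_days = 4,
                              t_ref = 15, t0 = -42.02, rref_floor = 1e-6) {
  assert_half_hourly(series, c("timestamp", "nee", "ta"))
  if (inherits(e0, "e0_estimate")) {
    t_ref <- e0$t_ref
    t0 <- e0$t0
    e0 <- e0$e0
  }
  ok <- night & is.finite(series$nee) & is.finite(series$ta)
  t_start <- min(series$timestamp)
  day_idx <- as.numeric(difftime(series$timestamp, t_start, units = "days"))
  win <- floor(day_idx / window_days)

  f <- lt_shape(series$ta, e0, t_ref, t0)
  est <- tibble(win = win[ok], nee = series$nee[ok], f = f[ok]) %>%
    group_by(.data$win) %>%
    summarise(rref = sum(.data$nee * .data$f) / sum(.data$f^2),
              n = n(), .groups = "drop")
  est$rref <- pmax(est$rref, rref_floor)
  # window centres in day units, then interpolate to every half hour
  centres <- (est$win + 0.5) * window_days
  rref_hh <- if (nrow(est) == 1) {
    rep(est$rref, nrow(series))
  } else {
    approx(centres, est$rref, xout = day_idx, rule = 2)$y
  }
  tibble(timestamp = series$timestamp, reco_ref = pmax(rref_hh, rref_floor))
}

#' Partition net ecosystem exchange into respiration and gross uptake
#'
#' Applies the nighttime partitioning convention: at night GPP is zero and
#' NEE is respiration; by day GPP is the modelled respiration minus NEE.
#' The returned `reco` and `gpp` columns satisfy `nee = reco - gpp` exactly
#' at every record: at night `reco` equals the (gap-filled) NEE itself,
#' by day it is the Lloyd-Taylor extrapolation `reco_model` except where a
#' negative GPP was clipped to zero (there `reco = nee`). The modelled
#' trajectory is kept in `reco_model`.
#'
#' @param series Half-hourly tibble with a complete (gap-filled) `nee` and
#'   `ta` column.
#' @param reco_model Numeric vector of modelled respiration at every record,
#'   e.g. `lloyd_taylor(series$ta, p)` with `reco_ref` replaced by the
#'   [estimate_reco_ref()] trajectory.
#' @param night Logical nighttime mask.
#' @return The series with columns `reco_model`, `reco`, `gpp` added and an
#'   attribute `n_gpp_clipped` counting daytime records where `reco_model`
#'   fell below NEE.
#' @export
partition_nee <- function(series, reco_model, night) {
  assert_half_hourly(series, c("timestamp", "nee"))
  if (length(reco_model) != nrow(series)) {
    abort("`reco_model` must have one value per record")
  }
  if (any(!is.finite(series$nee))) {
    abort("`nee` must be gap-filled before partitioning")
  }
  gpp <- ifelse(night, 0, reco_model - series$nee)
  clipped <- !night & gpp < 0
  gpp[clipped] <- 0
  out <- series
  out$reco_model <- reco_model
  # identity-consistent respiration: nee + gpp
  out$reco <- series$nee + gpp
  out$gpp <- gpp
  attr(out, "n_gpp_clipped") <- sum(clipped)
  out
}

#' Fit the rectangular-hyperbola light response of daytime NEE
#'
#' Nonlinear least-squares fit of
#' `nee ~ alpha * beta * rg / (alpha * rg + beta) + gamma` to daytime
#' records. Starting values: `gamma` from the mean NEE at low light,
#' `beta` from the mean NEE at high light minus `gamma`, `alpha` from the
#' initial slope. Non-convergence is an error with diagnostics, never a
#' silent default.
#'
#' @param series Tibble with `nee` and `rg` columns (daytime records).
#' @param min_n Minimum number of pairs (default 30).
#' @param min_rg_range Minimum span of `rg` in W m⁻² (default 300).
#' @return An object of class `light_response` with elements `params`
#'   ([lr_params()]), `fit` (the `nls` object), `rmse` and `n`. Supports
#'   [generics::tidy()], [generics::glance()], `predict()` and
#'   [autoplot.light_response()].
#' @export
fit_light_response <- function(series, min_n = 30, min_rg_range = 300) {
  assert_half_hourly(series, c("nee", "rg"))
  dat <- series[is.finite(series$nee) & is.finite(series$rg) & series$rg > 0,
                c("nee", "rg")]
  if (nrow(dat) < min_n) {
    abort(sprintf("need >= %d daytime pairs with rg > 0, got %d",
                  min_n, nrow(dat)))
  }
  if (diff(range(dat$rg)) < min_rg_range) {
    abort(sprintf("rg must span >= %g W m⁻² (got %.1f): no light range to fit",
                  min_rg_range, diff(range(dat$rg))))
  }
  lo <- dat$rg <= quantile(dat$rg, 0.2)
  hi <- dat$rg >= quantile(dat$rg, 0.8)
  g0 <- max(mean(dat$nee[lo]), 0.1)
  b0 <- min(mean(dat$nee[hi]) - g0, -0.5)
  a0 <- min((mean(dat$nee[lo]) - g0) / max(mean(dat$rg[lo]), 1), -1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      nee ~ alpha * beta * rg / (alpha * rg + beta) + gamma,
      data = dat,
      start = list(alpha = a0, beta = b0, gamma = g0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(paste0("light-response fit failed to converge: ",
                   conditionMessage(e),
                   sprintf(" [n = %d, rg range %.0f-%.0f W m⁻²]",
                           nrow(dat), min(dat$rg), max(dat$rg))))
    }
  )
  est <- coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  structure(
    list(params = lr_params(est[["alpha"]], est[["beta"]], est[["gamma"]],
                            rmse = rmse, n = nrow(dat)),
         fit = fit, rmse = rmse, n = nrow(dat), data = dat),
    class = "light_response"
  )
}

#' Predict NEE from a fitted light response
#'
#' @param object A `light_response` fit.
#' @param rg Global radiation (W m⁻²); defaults to the training data.
#' @param ... Unused.
#' @export
predict.light_response <- function(object, rg = NULL, ...) {
  p <- object$params
  if (is.null(rg)) rg <- object$data$rg
  p$alpha * p$beta * rg / (p$alpha * rg + p$beta) + p$gamma
}

#' @export
print.light_response <- function(x, ...) {
  p <- x$params
  cat("Rectangular-hyperbola light response (n =", x$n, ")\n")
  cat(sprintf("  alpha = %.4f µmol C J⁻¹ (initial slope)\n", p$alpha))
  cat(sprintf("  beta  = %.2f µmol C m⁻² s⁻¹ (saturation uptake)\n", p$beta))
  cat(sprintf("  gamma = %.2f µmol C m⁻² s⁻¹ (respiration offset)\n", p$gamma))
  cat(sprintf("  RMSE  = %.3f µmol m⁻² s⁻¹\n", x$rmse))
  invisible(x)
}

#' @export
print.e0_estimate <- function(x, ...) {
  cat(sprintf("E0 = %.1f ± %.1f K (%d of %d windows accepted)\n",
              x$e0, x$se, sum(x$windows$accepted), nrow(x$windows)))
  invisible(x)
}
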