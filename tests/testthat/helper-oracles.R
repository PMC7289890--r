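# Independent oracles used across test files. These deliberately re-derive
# the quantities with the most literal (brute-force) formulation available,
# sharing no code with the package internals they check.

# two-pass population covariance: explicit means, then explicit products
oracle_two_pass_cov <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - mx) * (y[i] - my)
  s / n
}

# Exhaustive donor enumeration for MDS gap-filling: for a gap at index i,
# walks the window ladder and similarity conditions exactly as specified,
# via plain loops. Returns list(value, method, window, donors) or NULL.
oracle_mds_one_gap <- function(i, series, rg_tol = 50, ta_tol = 2.5,
                               vpd_tol_kpa = 0.5, rg_frac = 0.2,
                               ladder = c(7, 14, 28, 56, 112),
                               min_donors = 2) {
  n <- nrow(series)
  day <- as.numeric(difftime(series$timestamp, series$timestamp[1],
                             units = "days"))
  valid <- which(is.finite(series$nee))
  has_met <- is.finite(series$rg[i]) && is.finite(series$ta[i]) &&
    is.finite(series$vpd[i])
  has_rg <- is.finite(series$rg[i])
  tol_rg <- min(rg_tol, rg_frac * abs(series$rg[i]))

  scan <- function(full_met) {
    for (w in ladder) {
      donors <- integer(0)
      for (j in valid) {
        if (j == i) next
        if (abs(day[j] - day[i]) > w) next
        if (!is.finite(series$rg[j])) next
        if (abs(series$rg[j] - series$rg[i]) > tol_rg) next
        if (full_met) {
          if (!is.finite(series$ta[j]) || !is.finite(series$vpd[j])) next
          if (abs(series$ta[j] - series$ta[i]) > ta_tol) next
          if (abs(series$vpd[j] - series$vpd[i]) > vpd_tol_kpa) next
        }
        donors <- c(donors, j)
      }
      if (length(donors) >= min_donors) {
        return(list(value = mean(series$nee[donors]),
                    method = if (full_met) "full-met" else "rg-only",
                    window = w, donors = donors))
      }
    }
    NULL
  }

  res <- NULL
  if (has_met) res <- scan(TRUE)
  if (is.null(res) && has_rg) res <- scan(FALSE)
  if (is.null(res)) {
    hr <- function(t) lubridate::hour(t) + lubridate::minute(t) / 60
    dh <- abs(hr(series$timestamp) - hr(series$timestamp[i]))
    dh <- pmin(dh, 24 - dh)
    for (w in sort(unique(c(1, 2, 4, ladder)))) {
      donors <- setdiff(valid[abs(day[valid] - day[i]) <= w &
                                dh[valid] <= 1], i)
      if (length(donors) >= min_donors) {
        return(list(value = mean(series$nee[donors]),
                    method = "diurnal-mean", window = w, donors = donors))
      }
    }
    donors <- valid[dh[valid] <= 1]
    res <- list(value = mean(series$nee[donors]), method = "diurnal-mean",
                window = Inf, donors = donors)
  }
  res
}

# small periodic noiseless series: an exact daily cycle repeated n_days
# times, so every same-clock record is an exact met match
make_periodic_series <- function(n_days = 30, year = 2014) {
  ts <- hh_grid(year)[seq_len(n_days * 48)]
  slot <- rep(seq_len(48), n_days)
  rg <- pmax(0, 900 * sin(pi * (slot - 12) / 24))  # daylight slots 13..36
  ta <- 25 + 5 * sin(pi * (slot - 16) / 24)
  vpd <- pmax(0.1, 1.5 + 1 * sin(pi * (slot - 18) / 24))
  nee <- 2 - 10 * rg / (rg + 400)
  tibble::tibble(timestamp = ts, nee = nee, rg = rg, ta = ta,
                 ts = ta + 2, rh = 60, vpd = vpd, precip = 0,
                 ustar = 0.3, pa = 99000)
}

# default synthetic year with truth, cached per test run
synthetic_year <- local({
  cache <- new.env()
  function(seed = 11, noise = 0, supp = 0.25) {
    key <- paste0("s", seed, "_", noise, "_", supp)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- site_config(seed = seed, noise_sd_nee = noise,
                       ustar_suppression_threshold = supp)
    met <- simulate_met_year(cfg)
    tb <- simulate_true_fluxes(met, config = cfg)
    cache[[key]] <- tb
    tb
  }
})
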