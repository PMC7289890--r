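test_that("Lloyd-Taylor evaluation matches hand-derived values and limits", {
  p <- lt_params(reco_ref = 2, e0 = 150)
  # exponent vanishes at the reference temperature
  expect_equal(lloyd_taylor(15, p), 2, tolerance = 1e-15)
  # hand evaluation at 25 °C
  expect_equal(lloyd_taylor(25, p), 2 * exp(150 * (1 / 57.02 - 1 / 67.02)),
               tolerance = 1e-12)
  # flat response at e0 = 0
  p0 <- lt_params(reco_ref = 2, e0 = 0)
  expect_equal(lloyd_taylor(c(-10, 0, 25, 40), p0), rep(2, 4))
  # strictly increasing and positive
  ta <- seq(-30, 45, by = 0.5)
  r <- lloyd_taylor(ta, p)
  expect_true(all(r > 0))
  expect_true(all(diff(r) > 0))
  # domain guards
  expect_error(lloyd_taylor(-43, p), "t0")
  expect_error(lloyd_taylor(300, p), "Kelvin")
})

# noiseless nighttime records generated straight from the model
lt_night_series <- function(e0 = 150, rref = 2, n_days = 365, seed = 8,
                            noise = 0) {
  set.seed(seed)
  ts <- hh_grid(2014)
  night <- rep(c(rep(TRUE, 12), rep(FALSE, 24), rep(TRUE, 12)), n_days)
  doy <- rep(seq_len(n_days), each = 48)
  ta <- 22 + 4 * cos(2 * pi * (doy - 330) / 365) +
    3 * sin(2 * pi * seq_along(doy) / 48) + rnorm(length(doy), 0, 1.5)
  nee <- rref * exp(e0 * (1 / 57.02 - 1 / (ta + 42.02))) +
    rnorm(length(ta), 0, noise)
  s <- tibble::tibble(timestamp = ts[seq_along(ta)], nee = nee, ta = ta,
                      rg = ifelse(night, 0, 500))
  list(series = s, night = night)
}

test_that("E0 is recovered from noiseless nighttime data within 1%", {
  d <- lt_night_series(e0 = 150, noise = 0)
  est <- estimate_e0(d$series, d$night)
  expect_lt(abs(est$e0 - 150) / 150, 0.01)
  expect_s3_class(tidy(est), "tbl_df")
  expect_equal(glance(est)$e0, est$e0)
})

test_that("E0 recovery stays within 15% under measurement noise (median over seeds)", {
  errs <- vapply(1:20, function(s) {
    d <- lt_night_series(e0 = 150, noise = 1, seed = s)
    est <- estimate_e0(d$series, d$night)
    abs(est$e0 - 150) / 150
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("isothermal nights are rejected as unidentifiable", {
  d <- lt_night_series(e0 = 150, noise = 0)
  d$series$ta <- 20
  expect_error(estimate_e0(d$series, d$night), "E0")
})

test_that("reference respiration trajectory is recovered and scales linearly", {
  d <- lt_night_series(e0 = 150, rref = 2, noise = 0)
  rr <- estimate_reco_ref(d$series, d$night, e0 = 150)
  expect_true(all(abs(rr$reco_ref - 2) / 2 < 0.05))
  # doubling nighttime NEE doubles the scale
  d2 <- d
  d2$series$nee <- 2 * d$series$nee
  rr2 <- estimate_reco_ref(d2$series, d2$night, e0 = 150)
  expect_equal(rr2$reco_ref, 2 * rr$reco_ref, tolerance = 1e-10)
})

test_that("a single window equals the closed-form least-squares ratio", {
  d <- lt_night_series(e0 = 150, rref = 2, n_days = 3, noise = 0.3)
  rr <- estimate_reco_ref(d$series, d$night, e0 = 150, window_days = 10)
  f <- exp(150 * (1 / 57.02 - 1 / (d$series$ta + 42.02)))
  ok <- d$night & is.finite(d$series$nee)
  want <- sum(d$series$nee[ok] * f[ok]) / sum(f[ok]^2)
  expect_equal(unique(rr$reco_ref), want, tolerance = 1e-12)
})

test_that("partitioning enforces the identity and the nighttime regime", {
  d <- lt_night_series(noise = 0.5)
  s <- d$series
  s$nee[!d$night] <- s$nee[!d$night] - 8   # daytime uptake
  reco_model <- lloyd_taylor(s$ta, lt_params(reco_ref = 2, e0 = 150))
  out <- partition_nee(s, reco_model, d$night)
  expect_identical(out$nee, out$reco - out$gpp)
  expect_true(all(out$gpp[d$night] == 0))
  expect_true(all(out$gpp >= 0))
  expect_gte(attr(out, "n_gpp_clipped"), 0)
  # day record arithmetic: nee = -8, reco = 1.5 -> gpp = 9.5
  one <- partition_nee(tibble::tibble(timestamp = s$timestamp[1],
                                      nee = -8), 1.5, FALSE)
  expect_equal(one$gpp, 9.5)
  expect_equal(one$reco, 1.5)
  # gap-filled input required
  s$nee[5] <- NA
  expect_error(partition_nee(s, reco_model, d$night), "gap-filled")
})

test_that("light-response fitting recovers exact hyperbola parameters", {
  set.seed(12)
  rg <- runif(300, 5, 1000)
  p <- lr_params(alpha = -0.04, beta = -15, gamma = 2)
  nee <- p$alpha * p$beta * rg / (p$alpha * rg + p$beta) + p$gamma
  fit <- fit_light_response(tibble::tibble(nee = nee, rg = rg))
  expect_equal(fit$params$alpha, -0.04, tolerance = 1e-6)
  expect_equal(fit$params$beta, -15, tolerance = 1e-6)
  expect_equal(fit$params$gamma, 2, tolerance = 1e-6)
  expect_lt(fit$rmse, 1e-8)
  # algebraic limits: gamma at rg = 0, beta + gamma as rg -> infinity
  expect_equal(predict(fit, 0), 2, tolerance = 1e-6)
  expect_equal(predict(fit, 1e9), -15 + 2, tolerance = 1e-3)
  # tidy/glance/autoplot surface
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha", "beta", "gamma"))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("light-response preconditions are enforced", {
  expect_error(fit_light_response(tibble::tibble(nee = rnorm(50),
                                                 rg = rep(0, 50))),
               "daytime")
  expect_error(fit_light_response(tibble::tibble(nee = rnorm(50),
                                                 rg = runif(50, 100, 150))),
               "span")
})

test_that("a noiseless synthetic year is partitioned back to the truth", {
  tb <- synthetic_year(seed = 11, noise = 0, supp = 0)
  s <- tb$series
  night <- flag_nighttime(s)
  est <- estimate_e0(s, night)
  rr <- estimate_reco_ref(s, night, est)
  reco_model <- rr$reco_ref * dryflux:::lt_shape(s$ta, est$e0, 15, -42.02)
  out <- partition_nee(s, reco_model, night)
  expect_lt(max(abs(out$nee - (out$reco - out$gpp))), 1e-12)
  rel_rms <- sqrt(mean((out$gpp - tb$truth$true_gpp)^2)) /
    sqrt(mean(tb$truth$true_gpp^2))
  expect_lt(rel_rms, 0.02)
  # generating parameters recovered
  expect_lt(abs(est$e0 - 150) / 150, 0.05)
})
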