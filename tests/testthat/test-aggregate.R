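test_that("unit conversion matches hand arithmetic and round-trips", {
  expect_identical(umol_to_gC(0), 0)
  expect_equal(umol_to_gC(1, 86400), 1.0378, tolerance = 1e-4)
  expect_equal(umol_to_gC(1, 1800), 0.021620, tolerance = 1e-5)
  x <- c(-12.3, 0, 2.1, 8.6)
  expect_equal(gC_to_umol(umol_to_gC(x)), x, tolerance = 1e-12)
})

test_that("a constant flux integrates to the expected annual total", {
  s <- tibble::tibble(timestamp = hh_grid(2014), nee = -1)
  out <- suppressMessages(daily_and_seasonal_sums(s, vars = "nee", n_boot = 0))
  ann <- out$sum[out$season == "annual"]
  expect_equal(ann, -1 * 1800 * 48 * 365 * 12.011e-6, tolerance = 1e-12)
  expect_equal(ann, -378.8, tolerance = 1e-3)
  # constant daily sums: zero dispersion
  expect_equal(out$sd_daily[out$season == "annual"], 0)
})

test_that("seasonal sums partition the annual sum exactly", {
  tb <- synthetic_year(seed = 11, noise = 0, supp = 0)
  s <- tb$series
  s$gpp <- tb$truth$true_gpp
  s$reco <- tb$truth$true_reco
  out <- suppressMessages(daily_and_seasonal_sums(s, n_boot = 0))
  for (v in c("nee", "gpp", "reco")) {
    seas <- out$sum[out$variable == v & out$season != "annual"]
    ann <- out$sum[out$variable == v & out$season == "annual"]
    expect_equal(sum(seas), ann, tolerance = 1e-12)
  }
  # day counts cover the year exactly once
  expect_equal(sum(out$n_days[out$variable == "nee" &
                                out$season != "annual"]), 365)
})

test_that("carbon-use efficiency reproduces the published ratios", {
  expect_equal(carbon_use_efficiency(-169.0, -414.7), 0.41)
  expect_equal(carbon_use_efficiency(-145.0, -334.0), 0.43)
  expect_equal(carbon_use_efficiency(-100, -100), 1)
  # scale invariance
  expect_equal(carbon_use_efficiency(-3 * 169.0, -3 * 414.7),
               carbon_use_efficiency(-169.0, -414.7))
  expect_error(carbon_use_efficiency(-100, 0), "undefined")
})

test_that("window means recover planted values and degenerate windows", {
  s <- tibble::tibble(timestamp = hh_grid(2014)[1:480], nee = 5)
  out <- window_mean(s, "10:00", "12:00")
  expect_equal(out$mean[out$season == "annual"], 5)
  expect_equal(out$sd[out$season == "annual"], 0)
  # a full-day window equals the plain mean
  s2 <- tibble::tibble(timestamp = hh_grid(2014)[1:480],
                       nee = rnorm(480))
  full <- window_mean(s2, "00:00", "00:00")
  expect_equal(full$mean[full$season == "annual"], mean(s2$nee))
  # midnight-wrapping window picks the right clock slots
  s3 <- tibble::tibble(timestamp = hh_grid(2014)[1:48],
                       nee = seq_len(48))
  w <- window_mean(s3, "22:00", "00:00")
  # end-of-interval stamps 22:30..00:00 are slots 45..48 of the clock day,
  # i.e. records 44..47 of the first grid day plus record 48 (00:00)
  hrs <- dryflux:::clock_hour(s3$timestamp)
  hrs[hrs == 0] <- 24
  expect_equal(w$mean[w$season == "annual"],
               mean(s3$nee[hrs > 22 & hrs <= 24]))
  # planted midday plateau
  tb <- synthetic_year(seed = 11, noise = 0, supp = 0)
  s4 <- tb$series
  hrs4 <- dryflux:::clock_hour(s4$timestamp)
  s4$nee[hrs4 > 10 & hrs4 <= 12] <- -12
  out4 <- window_mean(s4, "10:00", "12:00")
  expect_equal(out4$mean[out4$season == "wet"], -12)
  expect_error(window_mean(s4, "10:00", "10:00"), "empty|window")
})

test_that("bootstrap CI behaves like a percentile interval of the mean", {
  # constant data: zero width at the constant
  ci <- bootstrap_ci(rep(3, 20), seed = 1)
  expect_equal(c(ci$lo, ci$mean, ci$hi), c(3, 3, 3))
  # reproducibility
  x <- rnorm(50)
  expect_identical(bootstrap_ci(x, seed = 7), bootstrap_ci(x, seed = 7))
  # < 3 values: mean with undefined interval
  ci2 <- bootstrap_ci(c(1, 2))
  expect_true(ci2$flagged)
  expect_true(is.na(ci2$lo))
  # coverage: the CI contains the true mean in >= 90% of replications
  set.seed(99)
  hits <- vapply(1:200, function(k) {
    x <- rnorm(100)
    ci <- bootstrap_ci(x, n_boot = 400, seed = k)
    ci$lo <= 0 && 0 <= ci$hi
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("bootstrap CI width shrinks like 1/sqrt(n)", {
  set.seed(5)
  width <- vapply(c(25, 100, 400), function(n) {
    mean(vapply(1:30, function(k) {
      ci <- bootstrap_ci(rnorm(n), n_boot = 400, seed = k)
      ci$hi - ci$lo
    }, numeric(1)))
  }, numeric(1))
  expect_gt(width[1] / width[2], 1.6)
  expect_lt(width[1] / width[2], 2.6)
  expect_gt(width[2] / width[3], 1.6)
  expect_lt(width[2] / width[3], 2.6)
})

test_that("correlation matrix has the expected structure and planted signs", {
  tb <- synthetic_year(seed = 11, noise = 1, supp = 0)
  s <- tb$series
  # plant respiration proportional to gross uptake plus noise, in the
  # signed convention (uptake negative)
  set.seed(2)
  s$gpp <- -tb$truth$true_gpp
  s$reco <- 0.3 * tb$truth$true_gpp + rnorm(nrow(s), 0, 0.3)
  s$nee <- s$reco + s$gpp
  cors <- correlation_matrix(s)
  # unit diagonal, symmetry, r in [-1, 1]
  diag_rows <- cors[cors$var1 == cors$var2 & !cors$flagged, ]
  expect_true(all(diag_rows$r == 1))
  expect_true(all(abs(cors$r[!cors$flagged]) <= 1))
  wet <- cors[cors$season == "wet", ]
  pick <- function(a, b) wet$r[wet$var1 == a & wet$var2 == b]
  expect_equal(pick("nee", "gpp"), pick("gpp", "nee"))
  # planted dependences in the signed convention: NEE tracks GPP
  # (both negative with uptake), GPP opposes respiration, and more light
  # means more uptake (more negative GPP)
  expect_gt(pick("nee", "gpp"), 0)
  expect_lt(pick("gpp", "reco"), 0)
  expect_lt(pick("gpp", "rg"), 0)
})

test_that("degenerate correlations are flagged, exact lines recovered", {
  s <- tibble::tibble(timestamp = hh_grid(2014)[1:200],
                      nee = rnorm(200))
  s$gpp <- -s$nee
  s$reco <- 5   # zero variance
  cors <- correlation_matrix(s, vars = c("nee", "gpp", "reco"),
                             by_season = FALSE)
  expect_equal(cors$r[cors$var1 == "nee" & cors$var2 == "gpp"], -1)
  expect_true(all(cors$flagged[cors$var1 == "reco" | cors$var2 == "reco"]))
})
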