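test_that("simulated met year has the right structure and site statistics", {
  cfg <- site_config(seed = 2)
  met <- simulate_met_year(cfg)
  expect_equal(nrow(met), 17520)
  expect_true(all(met$rg >= 0))
  # nighttime radiation is zero by solar geometry
  sin_el <- dryflux:::sin_solar_elevation(
    met$timestamp - lubridate::dminutes(15), cfg$latitude)
  expect_true(all(met$rg[sin_el <= 0] == 0))
  # rainfall hits the annual target (scaled by construction) and is
  # concentrated in the wet season
  expect_equal(sum(met$precip), cfg$annual_rain_target, tolerance = 1e-9)
  expect_lt(abs(sum(met$precip) - 513) / 513, 0.15)
  md <- format(as.Date(met$timestamp), "%m-%d")
  in_wet <- dryflux:::md_in_interval(md, "01-15", "05-31")
  expect_gt(sum(met$precip[in_wet]) / sum(met$precip), 0.7)
  # vegetation index: range inside [0.16, 0.42], peak in/near the wet season
  expect_true(all(met$veg_index >= 0.16 & met$veg_index <= 0.42))
  peak_md <- md[which.max(met$veg_index)]
  expect_true(dryflux:::md_in_interval(peak_md, "01-15", "07-31"))
  # VPD consistent with Ta and RH through the Magnus formula
  es <- 0.61094 * exp(17.625 * met$ta / (met$ta + 243.04))
  expect_equal(met$vpd, pmax(es * (1 - met$rh / 100), 0), tolerance = 1e-12)
  # leap year handled
  expect_equal(nrow(simulate_met_year(site_config(year = 2016))), 17568)
})

test_that("degenerate amplitudes give constant Ta and pure solar-geometry Rg", {
  cfg <- site_config(seed = 5, ta_diurnal_amp = 0, ta_seasonal_amp = 0,
                     ta_noise_sd = 0, clearness_sd = 0,
                     annual_rain_target = 0.5)
  met <- simulate_met_year(cfg)
  expect_equal(diff(range(met$ta)), 0)
  sin_el <- pmax(dryflux:::sin_solar_elevation(
    met$timestamp - lubridate::dminutes(15), cfg$latitude), 0)
  day <- met$rg > 0
  ratio <- met$rg[day] / sin_el[day]
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("generator is bit-reproducible under a fixed seed", {
  a <- simulate_met_year(site_config(seed = 42))
  b <- simulate_met_year(site_config(seed = 42))
  expect_identical(a, b)
  c <- simulate_met_year(site_config(seed = 43))
  expect_false(identical(a$rg, c$rg))
})

test_that("true fluxes satisfy the partition identity and the night regime", {
  tb <- synthetic_year(seed = 11, noise = 0, supp = 0)
  expect_identical(tb$truth$true_nee,
                   tb$truth$true_reco - tb$truth$true_gpp)
  expect_equal(tb$series$nee, tb$truth$true_nee)  # noiseless, unsuppressed
  expect_true(all(tb$truth$true_gpp[tb$series$rg == 0] == 0))
  expect_true(all(tb$truth$true_gpp >= 0))
  expect_true(all(tb$truth$true_reco >= 0))
})

test_that("low-turbulence observation loss only affects calm nights", {
  tb <- synthetic_year(seed = 11, noise = 0, supp = 0.25)
  night <- tb$series$rg < 10
  calm <- night & tb$series$ustar < 0.25
  expect_equal(tb$series$nee[!calm], tb$truth$true_nee[!calm])
  expect_equal(tb$series$nee[calm],
               tb$truth$true_nee[calm] * tb$series$ustar[calm] / 0.25)
})

test_that("with no light and no noise, NEE is exactly respiration", {
  cfg <- site_config(seed = 3, noise_sd_nee = 0,
                     ustar_suppression_threshold = 0)
  met <- simulate_met_year(cfg)
  met$rg <- 0
  tb <- simulate_true_fluxes(met, config = cfg)
  expect_identical(tb$series$nee, tb$truth$true_reco)
})

test_that("generating respiration matches a hand evaluation of the model", {
  cfg <- site_config(seed = 3, noise_sd_nee = 0,
                     veg_index_range = c(0.299, 0.301))
  met <- simulate_met_year(cfg)
  met$ta <- 25
  met$veg_index <- 0.3   # unit scale after normalisation
  tb <- simulate_true_fluxes(met, lt = lt_params(reco_ref = 2, e0 = 150),
                             config = cfg)
  hand <- 2 * exp(150 * (1 / 57.02 - 1 / 67.02))
  expect_equal(unique(tb$truth$true_reco), hand, tolerance = 1e-12)
  expect_equal(hand, 2.961, tolerance = 5e-4)
})

test_that("gapped meteorology is refused by the flux generator", {
  cfg <- site_config(seed = 3)
  met <- simulate_met_year(cfg)
  met$ta[100] <- NA
  expect_error(simulate_true_fluxes(met, config = cfg), "gap-free")
})

test_that("an all-zero degradation spec is the identity", {
  tb <- synthetic_year(seed = 11, noise = 0)
  spec <- degradation_spec(gap_fraction = 0, spike_count = 0,
                           calm_night_fraction = 0)
  deg <- degrade_series(tb, spec)
  expect_identical(deg$series, tb$series)
  expect_equal(nrow(deg$ledger), 0)
})

test_that("degradation ledger is complete and counts match the request", {
  tb <- synthetic_year(seed = 11, noise = 0)
  spec <- degradation_spec(gap_fraction = 0.1, spike_count = 5,
                           calm_night_fraction = 0.1, seed = 9)
  deg <- degrade_series(tb, spec)
  led <- deg$ledger

  gaps <- led[led$type == "gap", ]
  expect_equal(nrow(gaps), round(0.1 * nrow(tb$series)))
  expect_true(all(is.na(deg$series$nee[gaps$index])))
  # every sentinel in the output appears in the ledger and vice versa
  expect_setequal(which(is.na(deg$series$nee)), gaps$index)

  spikes <- led[led$type == "spike", ]
  expect_equal(nrow(spikes), 5)
  mad_nee <- mad(tb$series$nee, na.rm = TRUE)
  for (k in seq_len(nrow(spikes))) {
    i <- spikes$index[k]
    w <- max(1, i - 24):min(nrow(tb$series), i + 24)
    loc_med <- median(tb$series$nee[w])
    expect_gte(abs(deg$series$nee[i] - loc_med), 10 * mad_nee)
  }

  calm <- led[led$type == "calm", ]
  expect_true(all(deg$series$ustar[calm$index] < 0.18))
  # reproducibility
  deg2 <- degrade_series(tb, spec)
  expect_identical(deg$series, deg2$series)
})

test_that("excessive gap fractions that erase all nights are refused", {
  tb <- synthetic_year(seed = 11, noise = 0)
  short <- tb$series[1:96, ]
  expect_error(
    degrade_series(short, degradation_spec(gap_fraction = 0.99, seed = 1,
                                           spike_count = 0,
                                           calm_night_fraction = 0)),
    "nighttime")
})

test_that("high-frequency blocks reproduce the target flux statistically", {
  # zero target: empirical covariance near zero
  b0 <- simulate_high_frequency_block(0, rho_air = 40, n = 18000, seed = 1)
  expect_lt(abs(block_covariance_flux(b0)), 1.5)
  # Monte-Carlo over seeds: mean recovered flux within 2 SE of the target
  fluxes <- vapply(1:200, function(s) {
    block_covariance_flux(
      simulate_high_frequency_block(-10, rho_air = 40, n = 18000, seed = s))
  }, numeric(1))
  se <- sd(fluxes) / sqrt(length(fluxes))
  expect_lt(abs(mean(fluxes) - (-10)), 2 * se + 1e-8)
  # n < 2 is an error
  expect_error(simulate_high_frequency_block(-10, n = 1), ">= 2")
})
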