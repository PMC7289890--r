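---
title: "Processing half-hourly CO2 fluxes from a seasonally dry tropical forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing half-hourly CO2 fluxes from a seasonally dry tropical forest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(dryflux)
```

# The problem

Eddy-covariance towers measure the net ecosystem exchange of CO2 (NEE,
µmol m⁻² s⁻¹, uptake negative) as the sum of a turbulent flux and a storage
term. Before the half-hourly record can be summed into a carbon balance it
must be despiked, screened for low-turbulence nights, gap-filled, and
partitioned into its two gross components — ecosystem respiration
(R~eco~) and gross primary production (GPP). `dryflux` implements this
chain for semiarid, seasonally dry tropical sites (Caatinga-type
ecosystems), where a single wet season drives most of the year's carbon
uptake and the vegetation state (leaf area, greenness) swings widely with
antecedent rainfall.

Every stage is an ordinary function from a half-hourly tibble to a
half-hourly tibble, so the pipeline is just a chain of calls (or one
`run_pipeline()`); fitted objects support `tidy()`/`glance()`, and plot
builders return ggplots.

# Flux computation

The turbulent flux of one 30-minute block is
$F_{CO_2} = \rho_{air}\,\overline{w'c'}$, the covariance between vertical
wind and CO2 concentration fluctuations times the molar air density.
`block_covariance_flux()` uses population (1/N) normalisation — a fixed,
documented choice; with 18,000 samples per block the distinction from the
1/(N−1) convention is far below measurement noise. Blocks are rotated by
per-block *double rotation* (`double_rotation()`): a yaw into the mean
wind, then a pitch that nulls the mean vertical wind. Double rotation was
chosen over a planar fit because it is deterministic per block and needs no
multi-week regression window; the choice matters little for the synthetic
data used here and is configurable ground for future work.

The storage term uses the discrete single-height approach,
$S_c = \Delta C \, z / ((R\,T_a/P_a)\,\Delta t)$, with ΔC the change in the
column-mean CO2 *mixing ratio* (µmol mol⁻¹) between consecutive half hours
and $R T_a / P_a$ the molar volume of air. The mixing-ratio unit is the
only dimensionally consistent reading of this expression. NEE is then
simply $F_{CO_2} + S_c$ (`assemble_nee()`).

# Quality control

**Despiking** (`despike_moving_median()`) separates the series into a
smooth part (centred 49-record moving median) and a residual; residuals
beyond 7 Gaussian-consistent MADs (1.4826 × moving MAD) are spikes,
blanked for later gap-filling (never interpolated), and the filter is
iterated to a fixed point. Two numerical guards matter in practice:
windows with zero MAD flag nothing (constant data are not spikes), and
day and night records are despiked as *separate streams* — the diurnal
cycle of NEE is otherwise the dominant "residual" and the daily extremes
would be flagged wholesale. On clean synthetic data the split design flags
essentially nothing; on data with planted spikes it recovers exactly the
planted positions.

**u\* filtering.** Calm nights underestimate the flux. The friction
velocity threshold is estimated per season by the moving point test
(`ustar_threshold_mpt()`): valid nighttime records are split into 6
air-temperature quantile classes, each into 20 u\* quantile classes, and a
temperature class's threshold is the mean u\* of the lowest class whose
mean NEE reaches 95% of the mean over all higher classes; the seasonal
threshold is the median over temperature classes, floored at
0.05 m s⁻¹. All class counts and the criterion are configurable; the
defaults follow the methodology's usual convention. Nighttime records
below the seasonal threshold are blanked (`apply_ustar_filter()`);
daytime records are never touched.

# Gap-filling (marginal distribution sampling)

`mds_fill()` fills each missing NEE value by the mean of donor records
measured under similar meteorology, preferring information-richer methods:

1. *full-met* — donors within ±50 W m⁻² of R~g~ (capped at 20% of the
   target's R~g~, so nighttime gaps only accept nighttime donors),
   ±2.5 °C of T~a~ and ±5 hPa of VPD, inside a ±7-day window;
2. *rg-only* — only the radiation tolerance, when T~a~ or VPD is missing;
3. *diurnal-mean* — same clock time ±1 h of adjacent days, when no
   meteorology is available.

If a window yields fewer than 2 donors it widens along the ladder 7, 14,
28, 56, 112 days; when a method is exhausted the next one is tried, ending
with a clock-time climatology, so a series with any valid NEE is always
fully filled. Fills are graded A (full-met ≤ 14 d), B (full-met > 14 d or
rg-only ≤ 14 d) or C — the grades, ladder and donor minimum are this
package's documented scheme. The VPD tolerance is stated in hPa (the
field's convention) and converted once at the configuration boundary;
the series itself stores kPa. Driver gaps are filled first by
`fill_meteorology()` using the diurnal-mean logic.

The implementation is checked against a brute-force oracle that enumerates
donors by literal loops; filled values agree to 1e−12.

# Partitioning

At night GPP is zero and NEE is respiration; respiration's temperature
response is the Lloyd–Taylor model
$$R_{eco} = R_{eco,ref}\,\exp\!\Big(E_0\Big(\tfrac{1}{T_{ref}-T_0}
  - \tfrac{1}{T_a-T_0}\Big)\Big),$$
with $T_{ref} = 15$ °C and $T_0 = -42.02$ °C, both in °C throughout (a
guard rejects Kelvin-scale inputs). $E_0$ is fitted by nonlinear least
squares on nighttime data in 15-day windows sliding by 5 days; windows
need ≥ 6 records spanning ≥ 5 °C (isothermal windows are unidentifiable),
estimates outside 30–450 K are discarded and the rest are combined by an
uncertainty-weighted mean. With $E_0$ fixed, $R_{eco,ref}$ is re-estimated
in 4-day windows as the closed-form least-squares scale of the temperature
shape, floored at a small positive value and interpolated to every half
hour — this lets the respiration base level track moisture and vegetation
state. The window scheme follows the nighttime-partitioning convention;
all spans are configurable.

`partition_nee()` then sets GPP = R~eco,model~ − NEE by day and 0 by
night, clipping negative daytime GPP to zero (with a reported count). The
reported `reco` column is defined as `nee + gpp` so that the accounting
identity NEE = R~eco~ − GPP holds at machine precision at *every* record;
at night this equals the (gap-filled) NEE itself, and the smooth
Lloyd–Taylor extrapolation is kept alongside as `reco_model`. On noisy
calm nights `reco` can therefore dip slightly negative even though
`reco_model` never does — the cost of keeping the identity exact.

The daytime light response $NEE = \alpha\beta R_g/(\alpha R_g+\beta) +
\gamma$ (`fit_light_response()`) is fitted by Levenberg–Marquardt least
squares with data-driven starting values; non-convergence or an
unidentifiable saturation (|β| ≥ 100) is an error with diagnostics, never
a silent default. Fits are meaningful within a season (stable vegetation
state); across a whole year the seasonal swing in canopy state mixes
hyperbolas of very different scale and the single-curve fit degenerates.

# Aggregation and uncertainty

Fluxes convert to carbon mass as `flux · dt · 12.011e-6` g C m⁻²
(12.011 g mol⁻¹ carbon). Daily sums (48 half hours, end-of-interval
timestamps) feed seasonal and annual means ± sd and cumulative sums;
incomplete days are excluded from means and prorated into sums with a
reported count. Seasons are configurable date intervals defaulting to wet
(Jan 15–May 31), wet–dry (Jun 1–Jul 31), dry (Aug 1–Nov 30) and dry–wet
(Dec 1–Jan 14, wrapping the year). Carbon-use efficiency is NEP/GPP =
(−NEE)/(−GPP) on the signed sums, reported to 2 decimals. Clock-window
means (`window_mean()`, e.g. 10:00–12:00 midday, 22:00–00:00 nighttime)
follow the end-of-interval convention: the 10:00–12:00 window collects the
stamps 10:30 through 12:00. A methods-text alternative (20:00–22:00
nighttime) exists in the literature; the default follows the results-table
convention and both are one argument away. Uncertainty on seasonal means
is a percentile bootstrap of daily values (1000 resamples, 95%,
seed-reproducible); percentile rather than BCa because the upstream
convention says only "bootstrapped". Pearson correlation matrices with
two-sided p-values (`correlation_matrix()`) flag zero-variance and
low-n pairs instead of failing.

# The synthetic-data generator

The study's tower data are not deposited, so the package carries a
generator that emulates the site's statistical structure with known
ground truth; every pipeline stage is validated against it.

`simulate_met_year()` builds a complete half-hourly year: radiation from
solar geometry at 6.6° S scaled by day-scale clearness (mean 0.65, sd
0.06, rain days heavily clouded — annual R~g~ ≈ 7,900 MJ m⁻², matching the
site's ≈ 8,000–8,250); air temperature with 28.9 °C mean, 5 °C diurnal and
1.8 °C seasonal amplitude; RH anti-phased with temperature and wetter in
the wet season; VPD from the Magnus saturation formula
`es = 0.61094·exp(17.625·Ta/(Ta+243.04))` kPa; rainfall as clustered
wet-season events scaled so the annual total equals the configured target
(513 mm, the study-year total) exactly; and a vegetation-state index —
a first-order filter of antecedent daily rainfall with a 30-day time
constant, rescaled to 0.16–0.42, emulating how satellite greenness tracks
rainfall with a lag.

`simulate_true_fluxes()` generates respiration as Lloyd–Taylor
(R~eco,ref~ = 1.4, E~0~ = 150 K) scaled by the normalised vegetation index,
and GPP as the rectangular hyperbola (α = −0.015 µmol J⁻¹,
β = −25 µmol m⁻² s⁻¹) scaled by the *squared* normalised index — leaf area
drives photosynthesis more strongly than respiration, which produces the
site-like wet/dry contrast. These defaults were fixed once against the
site's published aggregates: they yield midday NEE ≈ −9.3 (wet) and −3.2
(dry) µmol m⁻² s⁻¹, nighttime NEE ≈ 3.2/2.1, and an annual NEE near
−200 g C m⁻². The published midday means (−12.3 wet, −5.1 dry) cannot be
reproduced *simultaneously* with the published annual sums
(−169/−145 g C m⁻²) by any smooth diurnal model — a −12 midday with +3
nights integrates to roughly −2.5 g C m⁻² d⁻¹, far beyond the printed
−0.70 — so the defaults favour the annual budget and accept weaker midday
peaks. Observed NEE adds homoscedastic Gaussian noise (sd 1 µmol m⁻² s⁻¹
by default; the noise model is a stated choice, not an inference) and, at
night, a proportional flux loss below u\* = 0.25 m s⁻¹ — the defect the
moving point test exists to detect; the truth table always carries the
unsuppressed fluxes. `degrade_series()` adds missing-value gaps
(singletons plus blocks), spikes of known position and size, and calm
nights with redrawn low u\*, returning a complete defect ledger for test
assertions.

What the generator does *not* emulate: soil-moisture memory in
respiration, storm-scale rainfall realism, instrument drift,
heteroscedastic or autocorrelated noise, and footprint variability.
Passing tests therefore demonstrate the correctness of the algorithms and
their numerical contracts, not the field accuracy of any particular tower.

# Reproducibility and scale

All randomness flows through explicit integer seeds (generator configs,
degradation specs, bootstrap); reruns are bit-identical. The test-suite
problem sizes — one synthetic year (17,520 records) for end-to-end runs,
100 seeds for parameter-recovery medians, 1,000 random blocks for the
covariance oracle, ≤ 5,000 records for the brute-force gap-filling
oracle — were chosen as the smallest sizes at which the statistical checks
are stable.

# A worked pipeline

```{r, eval = FALSE}
cfg <- site_config(seed = 1)
met <- simulate_met_year(cfg)
tb  <- simulate_true_fluxes(met, config = cfg)
deg <- degrade_series(tb, degradation_spec(seed = 101))

res <- run_pipeline(deg$series, pipeline_config())
res                      # counts, annual sums, NEP/GPP
tidy(res$ustar)          # per-season u* thresholds
glance(res$e0)           # combined temperature sensitivity
res$summary              # seasonal/annual table with bootstrap CIs
```

# Known limitations

* Double rotation instead of planar fit; WPL and spectral corrections are
  out of scope (their formulas are instrument-specific).
* The MDS radiation tolerance is capped at 20% of the target's R~g~, so
  records at very low but nonzero radiation have few donors and fall
  through to wider windows or the diurnal mean.
* The E~0~ window scheme assumes enough cool/warm contrast within 15-day
  windows; in nearly isothermal climates the fixed-E~0~ fallback must be
  used.
* Whole-year light-response fits degenerate when vegetation state varies
  strongly; fit per season.
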