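#' High-frequency averaging block
#'
#' One 30-minute block of fast (e.g. 10 Hz) samples: the three wind
#' components (m s⁻¹), the CO₂ concentration `c` (µmol per mol of dry air)
#' and the molar air density needed to convert the kinematic covariance
#' into a flux.
#'
#' @param u,v,w Streamwise, lateral and vertical wind samples (m s⁻¹);
#'   `u` and `v` may be omitted (`NULL`) when only the covariance flux is
#'   needed.
#' @param c CO₂ concentration samples (µmol mol⁻¹).
#' @param rho_air Molar air density (mol m⁻³), > 0.
#' @param sampling_rate Samples per second (Hz), > 0.
#' @param start_time Block start time (POSIXct).
#' @return An object of class `hf_block` with a `data` tibble and metadata.
#' @export
hf_block <- function(u = NULL, v = NULL, w, c, rho_air,
                     sampling_rate = 10,
                     start_time = as.POSIXct("2014-01-01 12:00:00",
                                             tz = "UTC")) {
  if (length(w) < 2 || length(c) != length(w)) {
    abort("`w` and `c` must have equal length >= 2")
  }
  if (!is.null(u) && (length(u) != length(w) || length(v) != length(w))) {
    abort("wind components must all have the same length")
  }
  if (rho_air <= 0) abort("`rho_air` must be > 0")
  if (sampling_rate <= 0) abort("`sampling_rate` must be > 0")
  dat <- if (is.null(u)) tibble(w = w, c = c)
         else tibble(u = u, v = v, w = w, c = c)
  structure(list(data = dat, rho_air = rho_air,
                 sampling_rate = sampling_rate, start_time = start_time),
            class = "hf_block")
}

#' @export
print.hf_block <- function(x, ...) {
  cat(sprintf("High-frequency block: %d samples at %g Hz, rho_air = %g mol m⁻³\n",
              nrow(x$data), x$sampling_rate, x$rho_air))
  invisible(x)
}

#' Double rotation of a high-frequency wind block
#'
#' Rotates the wind vector of each sample so that the block-mean lateral
#' and vertical wind are zero: first a yaw rotation into the mean wind,
#' then a pitch rotation that nulls the mean vertical component. Scalar
#' samples are untouched; per-sample wind speed is conserved.
#'
#' @param block An [hf_block()] carrying all three wind components.
#' @return The rotated block, with attributes `yaw` and `pitch` (radians).
#'   A block with zero mean horizontal wind cannot be rotated and is an
#'   error (the averaging interval should be flagged).
#' @export
double_rotation <- function(block) {
  stopifnot(inherits(block, "hf_block"))
  if (!all(c("u", "v", "w") %in% names(block$data))) {
    abort("double rotation needs all three wind components")
  }
  u <- block$data$u; v <- block$data$v; w <- block$data$w
  ub <- mean(u); vb <- mean(v)
  if (sqrt(ub^2 + vb^2) < 1e-12) {
    abort("zero mean horizontal wind: rotation undefined, flag this block")
  }
  theta <- atan2(vb, ub)                      # yaw
  u1 <- u * cos(theta) + v * sin(theta)
  v1 <- -u * sin(theta) + v * cos(theta)
  phi <- atan2(mean(w), mean(u1))             # pitch
  u2 <- u1 * cos(phi) + w * sin(phi)
  w2 <- -u1 * sin(phi) + w * cos(phi)
  out <- block
  out$data$u <- u2
  out$data$v <- v1
  out$data$w <- w2
  attr(out, "yaw") <- theta
  attr(out, "pitch") <- phi
  out
}

#' Turbulent CO₂ flux of one block
#'
#' The covariance between fluctuations of vertical wind and CO₂
#' concentration, times the molar air density:
#' `F = rho_air * mean((w - mean(w)) * (c - mean(c)))`.
#' Population (1/N) normalisation is used throughout.
#'
#' @param block An [hf_block()].
#' @return Flux in µmol m⁻² s⁻¹.
#' @export
#' @examples
#' b <- hf_block(w = c(1, -1), c = c(10, 0), rho_air = 40)
#' block_covariance_flux(b)  # 200
block_covariance_flux <- function(block) {
  stopifnot(inherits(block, "hf_block"))
  if (nrow(block$data) < 2) abort("block must hold at least 2 samples")
  block$rho_air * pop_cov(block$data$w, block$data$c)
}

#' Storage term below the measurement height (discrete approach)
#'
#' Change of CO₂ held in the air column below the sensor between
#' consecutive averaging intervals, treating the concentration inside the
#' canopy as constant with height:
#' `Sc = delta_c * z / ((R * ta / pa) * delta_t)`,
#' where `R * ta / pa` is the molar volume of air (m³ mol⁻¹).
#'
#' @param delta_c Change in column CO₂ mixing ratio between consecutive
#'   half hours (µmol mol⁻¹ of dry air).
#' @param z Measurement height above ground (m), default 11.
#' @param ta Air temperature in kelvin.
#' @param pa Ambient pressure (Pa).
#' @param delta_t Averaging interval (s), default 1800.
#' @param R Universal gas constant (J mol⁻¹ K⁻¹).
#' @return Storage flux in µmol m⁻² s⁻¹ (vectorised).
#' @export
#' @examples
#' storage_term(10, z = 11, ta = 300, pa = 101325)  # ~2.482
storage_term <- function(delta_c, z = 11, ta, pa, delta_t = 1800,
                         R = 8.314462618) {
  if (any(z <= 0)) abort("`z` must be > 0")
  if (any(delta_t <= 0)) abort("`delta_t` must be > 0")
  finite <- is.finite(ta) & is.finite(pa)
  if (any(ta[finite] <= 0) || any(pa[finite] <= 0)) {
    abort("`ta` (K) and `pa` (Pa) must be positive")
  }
  delta_c * z / ((R * ta / pa) * delta_t)
}

#' Assemble net ecosystem exchange from its components
#'
#' `nee = f_co2 + s_c`, with the micrometeorological sign convention:
#' negative NEE is carbon uptake by the ecosystem. Non-finite inputs
#' propagate to a missing NEE.
#'
#' @param f_co2 Turbulent flux (µmol m⁻² s⁻¹).
#' @param s_c Storage term (µmol m⁻² s⁻¹).
#' @return Tibble with columns `f_co2`, `s_c`, `nee`.
#' @export
#' @examples
#' assemble_nee(-8.6, 0.5)
assemble_nee <- function(f_co2, s_c) {
  if (length(f_co2) != length(s_c)) {
    abort("`f_co2` and `s_c` must have the same length")
  }
  nee <- f_co2 + s_c
  nee[!is.finite(nee)] <- NA_real_
  tibble(f_co2 = f_co2, s_c = s_c, nee = nee)
}
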