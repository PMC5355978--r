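# Frozen shape parameters of the synthetic daylight sky and the pigment
# template (log-normal-type alpha band, asymmetric in log-wavelength).
# Calibrated once so that fitting the absorptance polynomial to this
# spectrum/template pair lands close to the canonical coefficients.
SKY_CCT_K <- 6500          # blackbody colour-temperature proxy
SKY_RAYLEIGH_EXP <- 4      # lambda^-4 scattering modulation
SKY_REF_NM <- 380          # reference wavelength for the modulation
TEMPLATE_SIGMA_LEFT <- 0.034   # log-wavelength width below the peak
TEMPLATE_SIGMA_RIGHT <- 0.080  # log-wavelength width above the peak
TEMPLATE_EDGE_NM <- 2          # decay scale (nm) beyond the 300-412 band

#' Synthetic UV-rich daylight spectrum
#'
#' Generates a smooth, strictly positive clear-sky photon radiance on a
#' 1 nm grid over 300--412 nm, shaped as a blackbody photon spectrum at a
#' correlated colour temperature multiplied by a Rayleigh-scattering
#' `lambda^-exponent` term. Optional multiplicative log-normal noise
#' (seeded) roughens the spectrum for robustness checks. This stands in
#' for a measured clear-sky irradiance spectrum; absolute scale is a free
#' parameter because the incident flux `N_i` is an input everywhere
#' downstream.
#'
#' @param cct_k Colour-temperature proxy in kelvin.
#' @param rayleigh_exponent Exponent of the scattering modulation.
#' @param scale Peak radiance, photons sr^-1 m^-2 nm^-1.
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   (0 = smooth, deterministic).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return A [spectral_radiance] object on the 300--412 nm grid.
#' @export
#' @examples
#' sky <- make_daylight_spectrum()
#' range(sky$radiance) > 0
make_daylight_spectrum <- function(cct_k = SKY_CCT_K,
                                   rayleigh_exponent = SKY_RAYLEIGH_EXP,
                                   scale = 1, noise_sd = 0, seed = 1L) {
  stopifnot(cct_k > 0, scale > 0, noise_sd >= 0)
  wl <- seq(UV_WINDOW[1], UV_WINDOW[2], by = 1)
  lam_m <- wl * 1e-9
  # photon radiance of a blackbody ~ 1 / (lambda^4 (e^{hc/lambda kT} - 1))
  bb <- 1 / (lam_m^4 * (exp(PLANCK_H * LIGHT_C / (lam_m * BOLTZ_K * cct_k)) - 1))
  rad <- bb * (wl / SKY_REF_NM)^(-rayleigh_exponent)
  rad <- rad / max(rad) * scale
  if (noise_sd > 0) {
    rad <- withr_seed(seed, function() {
      rad * exp(stats::rnorm(length(rad), 0, noise_sd))
    })
  }
  spectral_radiance(wl, rad)
}

# run fn() under a temporary RNG state restored afterwards
withr_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Monochromatic (delta) spectrum fixture
#'
#' Concentrates the whole radiance in the single 1 nm grid bin at
#' `lambda0`. Feeding it through the exact spectral pipeline reproduces
#' the monochromatic Beer--Lambert results.
#'
#' @param lambda0 Wavelength of the line, nm; must lie in \[300, 412\].
#' @param flux Total integrated radiance assigned to the line (trapezoidal
#'   integral over the grid equals this value).
#' @return A [spectral_radiance] object.
#' @export
make_delta_spectrum <- function(lambda0 = 335, flux = 1) {
  if (lambda0 < UV_WINDOW[1] || lambda0 > UV_WINDOW[2])
    stop("`lambda0` must lie within [", UV_WINDOW[1], ", ", UV_WINDOW[2],
         "] nm")
  wl <- seq(UV_WINDOW[1], UV_WINDOW[2], by = 1)
  rad <- rep(0, length(wl))
  i <- which.min(abs(wl - lambda0))
  # trapezoid weight of an interior grid point with 1 nm spacing is 1
  w <- if (i == 1 || i == length(wl)) 0.5 else 1
  rad[i] <- flux / w
  spectral_radiance(wl, rad)
}

#' Rhodopsin absorbance template
#'
#' Single alpha-band, log-normal-type template for the UV rhodopsin:
#' a Gaussian in log-wavelength with different widths on the short- and
#' long-wavelength sides of the peak (the long side is broader, as in
#' published visual-pigment templates), normalized to 1 at `lambda_max`
#' and decaying steeply beyond the 300--412 nm band, outside which
#' absorption is negligible.
#'
#' @param lambda Wavelength(s), nm.
#' @param lambda_max Peak wavelength, nm.
#' @return Relative absorbance in \[0, 1\].
#' @export
#' @examples
#' pigment_template(c(300, 335, 412))
pigment_template <- function(lambda, lambda_max = 335) {
  x <- log(lambda / lambda_max)
  s <- ifelse(x < 0, TEMPLATE_SIGMA_LEFT, TEMPLATE_SIGMA_RIGHT)
  core <- exp(-x^2 / (2 * s^2))
  taper <- rep(1, length(lambda))
  lo <- lambda < UV_WINDOW[1]
  hi <- lambda > UV_WINDOW[2]
  taper[lo] <- exp(-((UV_WINDOW[1] - lambda[lo]) / TEMPLATE_EDGE_NM)^2)
  taper[hi] <- exp(-((lambda[hi] - UV_WINDOW[2]) / TEMPLATE_EDGE_NM)^2)
  core * taper
}

#' Write a synthetic sky spectrum to CSV
#'
#' Emits the two-column schema accepted by [read_spectrum_csv()].
#'
#' @param path Output CSV path.
#' @param ... Passed to [make_daylight_spectrum()].
#' @return The path, invisibly.
#' @export
write_sky_csv <- function(path, ...) {
  sky <- make_daylight_spectrum(...)
  utils::write.csv(
    data.frame(wavelength_nm = sky$wavelength_nm,
               radiance_photons = sky$radiance),
    path, row.names = FALSE)
  invisible(path)
}
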