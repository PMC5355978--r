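#' Decompose partially polarized light along R7's microvillar axis
#'
#' A flux `N_i` with degree of polarization `d` and angle `theta` (degrees,
#' measured from R7's microvillar axis) splits into components parallel and
#' perpendicular to R7's microvilli:
#' `N_par = N_i (1 + d cos 2 theta) / 2`,
#' `N_perp = N_i (1 - d cos 2 theta) / 2`.
#'
#' @param total_flux Incident photon flux `N_i`, photons s^-1, >= 0.
#' @param degree Degree of polarization `d` in \[0, 1\].
#' @param angle Polarization angle `theta` in degrees.
#' @return An object of class `polarized_light` with fields `total_flux`,
#'   `degree`, `angle`, `n_par` and `n_perp` (`n_par + n_perp == N_i`).
#' @export
#' @examples
#' split_polarization(100, 1, 30)  # n_par 75, n_perp 25
split_polarization <- function(total_flux, degree, angle) {
  stopifnot(is.numeric(total_flux), all(total_flux >= 0),
            is.numeric(angle))
  if (any(degree < 0 | degree > 1))
    stop("`degree` must lie in [0, 1], got ", degree)
  cw <- cos(2 * angle * pi / 180)
  structure(list(total_flux = total_flux, degree = degree, angle = angle,
                 n_par = total_flux * (1 + degree * cw) / 2,
                 n_perp = total_flux * (1 - degree * cw) / 2),
            class = "polarized_light")
}

#' @rdname split_polarization
#' @export
polarized_light <- split_polarization

# assemble an absorption_rates object and check non-negativity
absorption_rates <- function(a_par7, a_perp7, a_par8, a_perp8, light) {
  comp <- c(a_par7 = a_par7, a_perp7 = a_perp7,
            a_par8 = a_par8, a_perp8 = a_perp8)
  if (any(comp < -1e-9))
    stop("negative absorption component; absorptance model used outside ",
         "its validity range")
  structure(list(a7 = a_par7 + a_perp7, a8 = a_par8 + a_perp8,
                 a_par7 = a_par7, a_perp7 = a_perp7,
                 a_par8 = a_par8, a_perp8 = a_perp8,
                 transmitted_par = light$n_par - a_par7 - a_par8,
                 transmitted_perp = light$n_perp - a_perp7 - a_perp8),
            class = "absorption_rates")
}

#' @export
print.absorption_rates <- function(x, ...) {
  cat(sprintf("Absorption rates (photons/s): A7 = %.6g, A8 = %.6g\n",
              x$a7, x$a8))
  cat(sprintf("  transmitted: par %.6g, perp %.6g\n",
              x$transmitted_par, x$transmitted_perp))
  invisible(x)
}

#' Monochromatic absorption rates in the tiered pair
#'
#' Beer--Lambert absorption of single-wavelength light in the tiered
#' R7/R8 pair. R7 absorbs the parallel component with coefficient `k_par`
#' and the perpendicular with `k_perp`; R8 receives what R7 transmits and,
#' because its microvilli are orthogonal to R7's, absorbs the components
#' with the coefficients swapped.
#'
#' @param geometry A [crp_geometry()] object.
#' @param light A [split_polarization()] object.
#' @param dichroic A [dichroic_absorption()] object supplying the
#'   single-wavelength coefficients `k_par`, `k_perp`.
#' @return An `absorption_rates` object with total and per-component rates
#'   for R7 and R8 plus the transmitted remainders.
#' @export
#' @examples
#' g <- crp_geometry(100, 0.5)
#' mono_absorption_rates(g, split_polarization(1e5, 1, 0))
mono_absorption_rates <- function(geometry, light,
                                  dichroic = dichroic_absorption()) {
  stopifnot(inherits(geometry, "crp_geometry"),
            inherits(light, "polarized_light"))
  if (geometry$l7 < 0 || geometry$l8 < 0) stop("negative tier length")
  kp <- dichroic$k_par; kq <- dichroic$k_perp
  l7 <- geometry$l7; l8 <- geometry$l8
  a_par7 <- (1 - exp(-kp * l7)) * light$n_par
  a_perp7 <- (1 - exp(-kq * l7)) * light$n_perp
  a_par8 <- exp(-kp * l7) * (1 - exp(-kq * l8)) * light$n_par
  a_perp8 <- exp(-kq * l7) * (1 - exp(-kp * l8)) * light$n_perp
  absorption_rates(a_par7, a_perp7, a_par8, a_perp8, light)
}

#' Broadband absorption rates in the tiered pair
#'
#' Absorption of broadband (skylight) illumination using an absorptance
#' model `F_a(kappa)`. R7's components are `F_a(kappa_par7) N_par` and
#' `F_a(kappa_perp7) N_perp`; R8's are differences of `F_a` at stacked
#' optical depths, e.g. `[F_a(kappa_par7 + kappa_perp8) -
#' F_a(kappa_par7)] N_par`, which accounts exactly for the spectral
#' filtering of the light R7 passes on.
#'
#' @inheritParams mono_absorption_rates
#' @param model Absorptance model; defaults to the canonical polynomial.
#' @return An `absorption_rates` object.
#' @export
broadband_absorption_rates <- function(geometry, light,
                                       dichroic = dichroic_absorption(),
                                       model = canonical_absorptance_model(dichroic)) {
  stopifnot(inherits(geometry, "crp_geometry"),
            inherits(light, "polarized_light"))
  kp7 <- dichroic$k_par * geometry$l7
  kq7 <- dichroic$k_perp * geometry$l7
  kp8 <- dichroic$k_par * geometry$l8
  kq8 <- dichroic$k_perp * geometry$l8
  a_par7 <- absorptance(model, kp7) * light$n_par
  a_perp7 <- absorptance(model, kq7) * light$n_perp
  a_par8 <- (absorptance(model, kp7 + kq8) - absorptance(model, kp7)) * light$n_par
  a_perp8 <- (absorptance(model, kq7 + kp8) - absorptance(model, kq7)) * light$n_perp
  absorption_rates(a_par7, a_perp7, a_par8, a_perp8, light)
}

#' Polarization sensitivity of R7 or R8
#'
#' The ratio between the maximum and the minimum transduction rate under
#' fully polarized light (`d = 1`) of constant intensity. For untwisted
#' microvilli the extremes are at `theta = 0` (R7's axis) and
#' `theta = 90` degrees: R7 peaks at 0, R8 (orthogonal microvilli) at 90.
#' Vanishing tier lengths are handled analytically: a vanishingly short
#' photoreceptor has PS equal to its dichroic ratio, and a vanishingly
#' short R8 behind an R7 of length `l7` has
#' `PS8 = delta * exp((k_par - k_perp) l7)` (monochromatic) or
#' `delta * F_a'(kappa_perp7) / F_a'(kappa_par7)` (broadband).
#'
#' @param photoreceptor 7 or 8.
#' @param geometry A [crp_geometry()] object.
#' @param dichroic A [dichroic_absorption()] object.
#' @param mode `"broadband"` (absorptance model) or `"monochromatic"`
#'   (Beer--Lambert at the peak wavelength).
#' @param model Absorptance model for broadband mode.
#' @param flux Incident flux used when `saturation = TRUE` (PS then depends
#'   on light level); ignored otherwise.
#' @param saturation Logical; compute PS from saturated transduction rates?
#' @param array,tau_ms Saturation model settings (see [transduce()]).
#' @return PS, a dimensionless ratio >= 1.
#' @export
#' @examples
#' g <- crp_geometry(100, 0.5)
#' polarization_sensitivity(7, g, mode = "monochromatic")  # 7.5
#' polarization_sensitivity(8, g, mode = "monochromatic")  # 13.9
polarization_sensitivity <- function(photoreceptor, geometry,
                                     dichroic = dichroic_absorption(),
                                     mode = c("broadband", "monochromatic"),
                                     model = canonical_absorptance_model(dichroic),
                                     flux = NULL, saturation = FALSE,
                                     array = microvillar_array(),
                                     tau_ms = 90) {
  mode <- match.arg(mode)
  stopifnot(photoreceptor %in% c(7, 8), inherits(geometry, "crp_geometry"))
  eps <- 1e-6  # below this tier length (um) use the analytic limit

  if (saturation) {
    if (is.null(flux))
      stop("`flux` is required when computing PS with saturation")
    m_max <- transduce(geometry, split_polarization(flux, 1, if (photoreceptor == 7) 0 else 90),
                       dichroic, model, array, tau_ms, saturation = TRUE)
    m_min <- transduce(geometry, split_polarization(flux, 1, if (photoreceptor == 7) 90 else 0),
                       dichroic, model, array, tau_ms, saturation = TRUE)
    num <- if (photoreceptor == 7) m_max$mean7 else m_max$mean8
    den <- if (photoreceptor == 7) m_min$mean7 else m_min$mean8
    if (den == 0) stop("degenerate geometry: zero minimum transduction rate")
    return(num / den)
  }

  kp <- dichroic$k_par; kq <- dichroic$k_perp
  l7 <- geometry$l7; l8 <- geometry$l8
  if (photoreceptor == 7) {
    if (l7 < eps) return(dichroic$delta)
    if (mode == "monochromatic")
      (1 - exp(-kp * l7)) / (1 - exp(-kq * l7))
    else
      absorptance(model, kp * l7) / absorptance(model, kq * l7)
  } else {
    if (l8 < eps) {
      # limit of the ratio of F_a differences as l8 -> 0
      if (mode == "monochromatic")
        return(dichroic$delta * exp((kp - kq) * l7))
      return(dichroic$delta * absorptance_deriv(model, kq * l7) /
               absorptance_deriv(model, kp * l7))
    }
    if (mode == "monochromatic") {
      (exp(-kq * l7) * (1 - exp(-kp * l8))) /
        (exp(-kp * l7) * (1 - exp(-kq * l8)))
    } else {
      (absorptance(model, kq * l7 + kp * l8) - absorptance(model, kq * l7)) /
        (absorptance(model, kp * l7 + kq * l8) - absorptance(model, kp * l7))
    }
  }
}

#' Birefringence phase advance along a rhabdomere
#'
#' `delta_phi = 2 pi l delta_n / lambda`. Used as a sanity check that form
#' birefringence is too small to redistribute power between the polarized
#' modes in DRA-length rhabdomeres.
#'
#' @param length_um Rhabdomere length, micrometres, > 0.
#' @param delta_n Refractive index difference between the modes, >= 0.
#' @param wavelength_nm Wavelength, nm, > 0.
#' @return Phase advance in radians.
#' @export
#' @examples
#' birefringence_phase(60, 1e-3, 335)  # about 1.125 rad
birefringence_phase <- function(length_um, delta_n, wavelength_nm) {
  stopifnot(length_um > 0, delta_n >= 0, wavelength_nm > 0)
  2 * pi * (length_um * 1e-6) * delta_n / (wavelength_nm * 1e-9)
}
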