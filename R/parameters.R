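#' Standard DRA model parameters
#'
#' Returns the parameter set used throughout the package for the blowfly
#' (*Calliphora vicina*) dorsal rim area: facet-lens F-ratio `F = 2`,
#' rhabdomere diameter `D_r = 1.55` um, unpolarized peak absorption
#' coefficient `k = 0.0075` um^-1, dichroic ratio `delta = 10`, rhodopsin
#' peak wavelength 335 nm, microvillar linear density 360 um^-1, dead time
#' 30 ms and integration time 90 ms.
#'
#' @return A named list with elements `geometry` ([optical_geometry()]),
#'   `dichroic` ([dichroic_absorption()]) and `array`
#'   ([microvillar_array()]).
#' @export
#' @examples
#' p <- dra_parameters()
#' p$dichroic$k_par / p$dichroic$k_perp  # the dichroic ratio, 10
dra_parameters <- function() {
  list(
    geometry = optical_geometry(f_ratio = 2, rhabdomere_diameter = 1.55),
    dichroic = dichroic_absorption(k_mean_peak = 0.0075, dichroic_ratio = 10,
                                   lambda_max = 335),
    array    = microvillar_array(microvilli_per_um = 360, dead_time_ms = 30,
                                 segment_um = 1)
  )
}

#' Facet-lens and rhabdomere optical geometry
#'
#' @param f_ratio F-ratio of the facet lens (focal length / diameter),
#'   dimensionless, > 0.
#' @param rhabdomere_diameter Rhabdomere diameter in micrometres, > 0.
#' @return An object of class `optical_geometry`.
#' @export
optical_geometry <- function(f_ratio = 2, rhabdomere_diameter = 1.55) {
  stopifnot(is.numeric(f_ratio), length(f_ratio) == 1L, f_ratio > 0,
            is.numeric(rhabdomere_diameter), length(rhabdomere_diameter) == 1L,
            rhabdomere_diameter > 0)
  structure(list(f_ratio = f_ratio,
                 rhabdomere_diameter = rhabdomere_diameter),
            class = "optical_geometry")
}

#' Dichroic absorption coefficients of a rhabdomere
#'
#' The rhabdomere absorbs light polarized parallel to its microvilli more
#' strongly than perpendicular light. The two peak absorption coefficients
#' are derived from the unpolarized mean `k = (k_par + k_perp) / 2` and the
#' dichroic ratio `delta = k_par / k_perp`:
#' `k_par = 2 k delta / (delta + 1)` and `k_perp = 2 k / (delta + 1)`.
#'
#' @param k_mean_peak Unpolarized peak absorption coefficient, um^-1, > 0.
#' @param dichroic_ratio Dichroic ratio `delta`, >= 1.
#' @param lambda_max Wavelength of peak absorption, nm.
#' @return An object of class `dichroic_absorption` with fields `k`,
#'   `delta`, `k_par`, `k_perp` (um^-1) and `lambda_max` (nm).
#' @export
#' @examples
#' dc <- dichroic_absorption(0.0075, 10)
#' (dc$k_par + dc$k_perp) / 2  # 0.0075
dichroic_absorption <- function(k_mean_peak = 0.0075, dichroic_ratio = 10,
                                lambda_max = 335) {
  stopifnot(is.numeric(k_mean_peak), k_mean_peak > 0,
            is.numeric(dichroic_ratio), dichroic_ratio >= 1,
            is.numeric(lambda_max), lambda_max > 0)
  structure(list(
    k = k_mean_peak,
    delta = dichroic_ratio,
    k_par = 2 * k_mean_peak * dichroic_ratio / (dichroic_ratio + 1),
    k_perp = 2 * k_mean_peak / (dichroic_ratio + 1),
    lambda_max = lambda_max
  ), class = "dichroic_absorption")
}

#' Geometry of the tiered central rhabdomere pair
#'
#' Splits a CRP of total length `l` into a distal R7 tier of length
#' `l * (1 - r8_fraction)` and a proximal R8 tier of length
#' `l * r8_fraction`.
#'
#' @param total_length Total CRP length `l` in micrometres, >= 0.
#' @param r8_fraction Fraction of the CRP occupied by R8, in \[0, 1\].
#' @return An object of class `crp_geometry` with fields `l`, `r8_fraction`,
#'   `l7` and `l8` (micrometres; `l7 + l8 == l` exactly).
#' @export
crp_geometry <- function(total_length = 100, r8_fraction = 0.5) {
  stopifnot(is.numeric(total_length), length(total_length) == 1L,
            total_length >= 0,
            is.numeric(r8_fraction), length(r8_fraction) == 1L)
  if (r8_fraction < 0 || r8_fraction > 1)
    stop("`r8_fraction` must lie in [0, 1], got ", r8_fraction)
  l8 <- total_length * r8_fraction
  structure(list(l = total_length, r8_fraction = r8_fraction,
                 l7 = total_length - l8, l8 = l8),
            class = "crp_geometry")
}

#' Microvillar array of a rhabdomere tier
#'
#' Each microvillus is one transduction unit: after producing a quantum bump
#' it is refractory for the dead time `t_d`. The default linear density,
#' 360 microvilli per micrometre, is 9e4 microvilli along a 250 um
#' rhabdomere.
#'
#' @param microvilli_per_um Microvillar linear density, um^-1, > 0.
#' @param dead_time_ms Microvillar dead time `t_d` in milliseconds, > 0.
#' @param segment_um Thickness of the discretization segments used by the
#'   saturation model, micrometres, > 0.
#' @return An object of class `microvillar_array`.
#' @export
microvillar_array <- function(microvilli_per_um = 360, dead_time_ms = 30,
                              segment_um = 1) {
  stopifnot(microvilli_per_um > 0, dead_time_ms > 0, segment_um > 0)
  structure(list(microvilli_per_um = microvilli_per_um,
                 dead_time_ms = dead_time_ms,
                 segment_um = segment_um),
            class = "microvillar_array")
}

#' Configuration of the opponent coding model
#'
#' Bundles the stimulus, geometry and noise settings used by the opponent
#' metrics ([opponent_response()], [discriminable_angles()],
#' [mutual_information()], [discriminability()]).
#'
#' @param total_length Total CRP length in micrometres.
#' @param r8_fraction Fraction of the CRP occupied by R8.
#' @param degree Degree of polarization `d` of the stimulus, in \[0, 1\].
#' @param flux Incident photon flux `N_i` at R7's entrance aperture,
#'   photons s^-1.
#' @param sigma_in_sq Intrinsic noise variance, contrast^2 for a 1 s
#'   integration; it enters the opponent variance as `2 sigma_in^2 / tau`.
#' @param tau_ms Integration time in milliseconds.
#' @param saturation Logical; model microvillar dead-time saturation?
#' @param dichroic A [dichroic_absorption()] object.
#' @param array A [microvillar_array()] object (used when `saturation` is
#'   `TRUE`).
#' @param model Absorptance model, an [absorptance_model] object or a plain
#'   function of kappa. Defaults to the canonical broadband polynomial
#'   ([canonical_absorptance_model()]).
#' @param theta_grid_n Number of uniform polarization-angle steps over
#'   \[0, 90\] degrees used by [discriminable_angles()].
#' @return An object of class `opponent_config`.
#' @export
#' @examples
#' cfg <- opponent_config(flux = 1e5)
#' discriminable_angles(cfg)
opponent_config <- function(total_length = 100, r8_fraction = 0.5,
                            degree = 0.1, flux = 1e5,
                            sigma_in_sq = 5e-5, tau_ms = 90,
                            saturation = FALSE,
                            dichroic = dichroic_absorption(),
                            array = microvillar_array(),
                            model = canonical_absorptance_model(),
                            theta_grid_n = 900) {
  stopifnot(degree >= 0, degree <= 1, flux >= 0, sigma_in_sq >= 0,
            tau_ms > 0, is.logical(saturation), theta_grid_n >= 2)
  if (saturation) {
    ratio <- tau_ms / array$dead_time_ms
    if (abs(ratio - round(ratio)) > 1e-9)
      stop("with saturation on, `tau_ms` (", tau_ms,
           ") must be an integer multiple of the dead time (",
           array$dead_time_ms, " ms)")
  }
  structure(list(
    geometry = crp_geometry(total_length, r8_fraction),
    degree = degree, flux = flux, sigma_in_sq = sigma_in_sq,
    tau_ms = tau_ms, saturation = saturation,
    dichroic = dichroic, array = array, model = model,
    theta_grid_n = theta_grid_n
  ), class = "opponent_config")
}

#' @export
print.opponent_config <- function(x, ...) {
  cat("Opponent coding configuration\n")
  cat(sprintf("  CRP: l = %g um, R8 fraction = %g (l7 = %g, l8 = %g)\n",
              x$geometry$l, x$geometry$r8_fraction,
              x$geometry$l7, x$geometry$l8))
  cat(sprintf("  stimulus: N_i = %g photons/s, d = %g\n", x$flux, x$degree))
  cat(sprintf("  noise: sigma_in^2 = %g, tau = %g ms, saturation %s\n",
              x$sigma_in_sq, x$tau_ms, if (x$saturation) "on" else "off"))
  invisible(x)
}

#' @export
print.dichroic_absorption <- function(x, ...) {
  cat(sprintf(
    "Dichroic absorption: k = %g um^-1, delta = %g (k_par = %.6g, k_perp = %.6g), lambda_max = %g nm\n",
    x$k, x$delta, x$k_par, x$k_perp, x$lambda_max))
  invisible(x)
}

#' @export
print.crp_geometry <- function(x, ...) {
  cat(sprintf("CRP geometry: l = %g um; R7 = %g um, R8 = %g um (R8 fraction %g)\n",
              x$l, x$l7, x$l8, x$r8_fraction))
  invisible(x)
}
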