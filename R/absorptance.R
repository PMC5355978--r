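# Coefficients of the canonical broadband absorptance polynomial for UV
# rhodopsin (peak 335 nm) viewing blue skylight:
#   F_a(kappa) = (1 - exp(-kappa)) (c0 + c1 kappa + c2 kappa^2)
CANONICAL_FA_COEF <- c(0.4697838, 0.05512361, -0.00291346)

#' Broadband absorptance model
#'
#' An absorptance model gives `F_a(kappa)`, the fraction of incident
#' broadband photons absorbed by a rhabdomere of optical depth
#' `kappa = k(lambda_max) * l`, as
#' `(1 - exp(-kappa)) * (c0 + c1 kappa + c2 kappa^2)`. The polynomial factor
#' captures the spectral broadening of the absorbed band with depth: deeper
#' tiers receive light depleted at the peak wavelength, so absorptance grows
#' more slowly than the monochromatic exponential.
#'
#' @param coefficients Numeric vector `c(c0, c1, c2)`.
#' @param kappa_max Upper end of the validity range in kappa; the
#'   polynomial is non-physical beyond the range it was fitted on.
#' @param max_rel_error Maximum relative error of the fit against the exact
#'   spectral calculation (NA for the canonical model, whose fit inputs are
#'   not re-derived here).
#' @return An object of class `absorptance_model`. It can be called
#'   directly as a function of kappa via [absorptance()].
#' @seealso [canonical_absorptance_model()], [fit_absorptance_polynomial()]
#' @export
absorptance_model <- function(coefficients, kappa_max, max_rel_error = NA_real_) {
  stopifnot(is.numeric(coefficients), length(coefficients) == 3,
            is.numeric(kappa_max), kappa_max > 0)
  structure(list(coefficients = unname(coefficients), kappa_max = kappa_max,
                 max_rel_error = max_rel_error),
            class = "absorptance_model")
}

#' @export
print.absorptance_model <- function(x, ...) {
  cat(sprintf(
    "Absorptance model F_a(kappa) = (1 - e^-kappa)(%.7g %+.7g kappa %+.7g kappa^2)\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  valid for kappa in [0, %.4g]", x$kappa_max))
  if (is.finite(x$max_rel_error))
    cat(sprintf("; max relative fit error %.3g", x$max_rel_error))
  cat("\n")
  invisible(x)
}

#' The canonical broadband absorptance model
#'
#' The printed polynomial approximation to the absorptance of blue skylight
#' by UV rhodopsin (peak 335 nm): relative error below 1% for rhabdomere
#' lengths up to 1 mm. All headline computations in this package use it, so
#' no spectral data are required.
#'
#' @param dichroic A [dichroic_absorption()] object; its unpolarized `k`
#'   sets the validity range `kappa_max = k * 1000 um`, the optical depth
#'   of a 1 mm rhabdomere. Beyond the fitted range the polynomial bracket
#'   eventually acquires a negative slope and the model turns
#'   non-physical, so arguments outside it are an error.
#' @return An [absorptance_model] object.
#' @export
canonical_absorptance_model <- function(dichroic = dichroic_absorption()) {
  absorptance_model(CANONICAL_FA_COEF, kappa_max = dichroic$k * 1000)
}

#' Evaluate a broadband absorptance model
#'
#' @param model An [absorptance_model] object, or a plain function of
#'   kappa (then called directly, without range checking).
#' @param kappa Optical depth(s) `k(lambda_max) * l`, dimensionless, >= 0.
#' @return Absorbed fraction(s) in \[0, 1\].
#' @export
#' @examples
#' absorptance(canonical_absorptance_model(), c(0, 1, 5))
absorptance <- function(model, kappa) {
  if (is.function(model)) return(model(kappa))
  stopifnot(inherits(model, "absorptance_model"))
  if (any(kappa < -1e-12 | kappa > model$kappa_max + 1e-9))
    stop("kappa outside the validity range [0, ", signif(model$kappa_max, 4),
         "] of the absorptance model")
  cf <- model$coefficients
  (1 - exp(-kappa)) * (cf[1] + cf[2] * kappa + cf[3] * kappa^2)
}

# derivative dF_a/dkappa, used for analytic zero-length limits
absorptance_deriv <- function(model, kappa) {
  if (is.function(model)) {
    h <- 1e-6
    return((model(kappa + h) - model(pmax(kappa - h, 0))) /
             (kappa + h - pmax(kappa - h, 0)))
  }
  cf <- model$coefficients
  exp(-kappa) * (cf[1] + cf[2] * kappa + cf[3] * kappa^2) +
    (1 - exp(-kappa)) * (cf[2] + 2 * cf[3] * kappa)
}

#' Canonical broadband absorptance
#'
#' Convenience wrapper evaluating the canonical polynomial
#' ([canonical_absorptance_model()]) at `kappa`.
#'
#' @param kappa Optical depth(s), dimensionless.
#' @return Absorbed fraction(s).
#' @export
canonical_absorptance <- function(kappa) {
  absorptance(canonical_absorptance_model(), kappa)
}

#' Exact broadband absorptance from a spectrum and pigment template
#'
#' Computes the fraction of incident photons absorbed by a rhabdomere of
#' length `length_um` whose absorption coefficient spectrum is
#' `k(lambda) = k_peak * template(lambda)`:
#' `F_a = (1/N_i) integral (1 - exp(-k(lambda) l)) R_i(lambda) dlambda`
#' over the 300--412 nm window.
#'
#' @param spectrum A [spectral_radiance] object (any overall scale; the
#'   result is a fraction).
#' @param template Function of wavelength (nm) returning relative
#'   absorbance in \[0, 1\], normalized to 1 at the peak. Defaults to
#'   [pigment_template()].
#' @param k_peak Peak absorption coefficient, um^-1.
#' @param length_um Rhabdomere length(s), micrometres, >= 0.
#' @return Absorbed fraction(s) in \[0, 1\].
#' @export
#' @examples
#' sky <- make_daylight_spectrum()
#' exact_absorptance(sky, length_um = c(0, 100, 1000))
exact_absorptance <- function(spectrum, template = pigment_template,
                              k_peak = 0.0075, length_um) {
  stopifnot(inherits(spectrum, "spectral_radiance"), k_peak > 0,
            all(length_um >= 0))
  wl <- spectrum$wavelength_nm
  keep <- wl >= UV_WINDOW[1] & wl <= UV_WINDOW[2]
  wl <- wl[keep]
  ri <- spectrum$radiance[keep]
  tpl <- template(wl)
  ni <- trapz_window(wl, ri)
  vapply(length_um, function(l) {
    trapz_window(wl, (1 - exp(-k_peak * tpl * l)) * ri) / ni
  }, numeric(1))
}

#' Fit the broadband absorptance polynomial
#'
#' Computes the exact absorptance ([exact_absorptance()]) at `n_samples`
#' optical depths spanning `(0, kappa_max]` and fits the model form
#' `(1 - exp(-kappa)) (c0 + c1 kappa + c2 kappa^2)` by weighted least
#' squares minimizing *relative* error. The achieved maximum relative error
#' is reported in the returned model and a warning is raised if it exceeds
#' `tol`.
#'
#' @inheritParams exact_absorptance
#' @param kappa_max Upper end of the fitted range; defaults to the optical
#'   depth of a 1 mm rhabdomere at `k_peak`.
#' @param n_samples Number of sample depths (>= 50 recommended).
#' @param tol Relative-error tolerance above which the fit is flagged.
#' @return An [absorptance_model] with `max_rel_error` filled in.
#' @export
fit_absorptance_polynomial <- function(spectrum, template = pigment_template,
                                       k_peak = 0.0075,
                                       kappa_max = k_peak * 1000,
                                       n_samples = 50, tol = 0.01) {
  stopifnot(n_samples >= 4, kappa_max > 0)
  kappa <- seq(kappa_max / n_samples, kappa_max, length.out = n_samples)
  fa <- exact_absorptance(spectrum, template, k_peak, kappa / k_peak)
  # dividing out (1 - e^-kappa) makes the model linear in the coefficients;
  # 1/y^2 weights turn least squares into relative-error minimization
  y <- fa / (1 - exp(-kappa))
  fit <- stats::lm(y ~ kappa + I(kappa^2), weights = 1 / y^2)
  cf <- unname(stats::coef(fit))
  model <- absorptance_model(cf, kappa_max)
  rel_err <- max(abs(absorptance(model, kappa) / fa - 1))
  model$max_rel_error <- rel_err
  if (rel_err > tol)
    warning(sprintf("absorptance fit exceeds tolerance: max relative error %.3g > %.3g",
                    rel_err, tol))
  model
}
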