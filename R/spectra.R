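# Physical constants (SI)
PLANCK_H <- 6.62607015e-34   # J s
LIGHT_C  <- 2.99792458e8     # m s^-1
BOLTZ_K  <- 1.380649e-23     # J K^-1

# Integration window of the UV rhodopsin, nm. Absorption is negligible
# outside it, so all spectral integrals run over [300, 412].
UV_WINDOW <- c(300, 412)

#' Tabulated spectral photon radiance
#'
#' @param wavelength_nm Strictly increasing wavelength grid in nm. Must
#'   cover the UV absorption window \[300, 412\] nm.
#' @param radiance Photon radiance at each grid point,
#'   photons sr^-1 m^-2 nm^-1, non-negative.
#' @return An object of class `spectral_radiance`.
#' @export
spectral_radiance <- function(wavelength_nm, radiance) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(radiance),
            length(wavelength_nm) == length(radiance),
            length(wavelength_nm) >= 2)
  if (any(diff(wavelength_nm) <= 0))
    stop("`wavelength_nm` must be strictly increasing")
  if (any(radiance < 0))
    stop("`radiance` must be non-negative everywhere")
  if (wavelength_nm[1] > UV_WINDOW[1] ||
      wavelength_nm[length(wavelength_nm)] < UV_WINDOW[2])
    stop("wavelength grid must cover the integration window [",
         UV_WINDOW[1], ", ", UV_WINDOW[2], "] nm")
  structure(list(wavelength_nm = wavelength_nm, radiance = radiance),
            class = "spectral_radiance")
}

#' @export
print.spectral_radiance <- function(x, ...) {
  cat(sprintf(
    "Spectral radiance: %d points over [%g, %g] nm, peak %.4g photons sr^-1 m^-2 nm^-1\n",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    max(x$radiance)))
  invisible(x)
}

# trapezoidal integral of y(x) restricted to [a, b]; the grid is assumed to
# contain points at or beyond both window edges
trapz_window <- function(x, y, a = UV_WINDOW[1], b = UV_WINDOW[2]) {
  keep <- x >= a & x <= b
  xs <- x[keep]; ys <- y[keep]
  if (length(xs) < 2) stop("fewer than two grid points inside [", a, ", ", b, "]")
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

#' Convert spectral irradiance to photon radiance
#'
#' Skylight radiance is modelled as that of an ideal Lambertian surface
#' under the measured irradiance, so the irradiance is divided by pi, and by
#' the quantal energy `h c / lambda` to convert watts to photons:
#' `L(lambda) = E(lambda) * lambda / (pi h c)`.
#'
#' @param wavelength_nm Strictly increasing wavelength grid, nm.
#' @param irradiance_W_m2_nm Spectral irradiance, W m^-2 nm^-1,
#'   non-negative.
#' @return A [spectral_radiance] object in photons sr^-1 m^-2 nm^-1.
#' @export
#' @examples
#' irradiance_to_radiance(c(300, 400, 412), c(0.5, 1, 1))
irradiance_to_radiance <- function(wavelength_nm, irradiance_W_m2_nm) {
  if (any(irradiance_W_m2_nm < 0))
    stop("`irradiance_W_m2_nm` must be non-negative")
  lambda_m <- wavelength_nm * 1e-9
  rad <- irradiance_W_m2_nm * lambda_m / (pi * PLANCK_H * LIGHT_C)
  spectral_radiance(wavelength_nm, rad)
}

#' Photon flux at R7's entrance aperture
#'
#' The facet lens focuses a small patch of sky onto the distal tip of R7.
#' The spectral photon flux there is
#' `(pi/4)^2 F^-2 D_r^2 L(lambda)`, with `D_r` in metres, and the total
#' incident flux `N_i` is its integral over the UV absorption window
#' 300--412 nm.
#'
#' @param spectrum A [spectral_radiance] object.
#' @param geometry An [optical_geometry()] object (`D_r` in micrometres).
#' @return Photon flux `N_i` in photons s^-1.
#' @export
#' @examples
#' sky <- make_daylight_spectrum(scale = 1e18)
#' photon_flux_at_aperture(sky, optical_geometry())
photon_flux_at_aperture <- function(spectrum, geometry = optical_geometry()) {
  stopifnot(inherits(spectrum, "spectral_radiance"),
            inherits(geometry, "optical_geometry"))
  dr_m <- geometry$rhabdomere_diameter * 1e-6
  gain <- (pi / 4)^2 * geometry$f_ratio^-2 * dr_m^2
  gain * trapz_window(spectrum$wavelength_nm, spectrum$radiance)
}

#' Read a spectral table from CSV
#'
#' Expects a header row with a wavelength column (name containing
#' "wavelength") and either an irradiance column (name containing
#' "irradiance", W m^-2 nm^-1, converted via [irradiance_to_radiance()]) or
#' a radiance column (name containing "radiance", photon units, used as is).
#'
#' @param path Path to a two-column CSV file.
#' @return A [spectral_radiance] object.
#' @export
read_spectrum_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- names(tab)
  wl_col <- grep("wavelength", nm, ignore.case = TRUE)
  if (length(wl_col) != 1)
    stop("expected exactly one column whose name contains 'wavelength'")
  irr_col <- grep("irradiance", nm, ignore.case = TRUE)
  rad_col <- grep("radiance", nm, ignore.case = TRUE)
  rad_col <- setdiff(rad_col, irr_col)
  if (length(irr_col) == 1) {
    irradiance_to_radiance(tab[[wl_col]], tab[[irr_col]])
  } else if (length(rad_col) == 1) {
    spectral_radiance(tab[[wl_col]], tab[[rad_col]])
  } else {
    stop("expected one column named like 'irradiance' or 'radiance'")
  }
}
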