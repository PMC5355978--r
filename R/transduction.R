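# segment boundaries for a tier of length L (um): full segments of
# `seg` um plus a trailing partial segment if L is not a multiple
segment_bounds <- function(L, seg) {
  if (L <= 0) return(numeric(0))
  b <- if (seg <= L) seq(seg, L, by = seg) else numeric(0)
  if (length(b) == 0 || L - b[length(b)] > 1e-12) b <- c(b, L)
  b
}

#' Per-segment absorption profile of the tiered pair
#'
#' Divides R7 and R8 into thin segments (default 1 um) and computes each
#' segment's absorption rate as a difference of the absorptance model at
#' stacked optical depths, so that distal filtering is exact and the
#' segment rates telescope to the whole-photoreceptor rates of
#' [broadband_absorption_rates()].
#'
#' @inheritParams broadband_absorption_rates
#' @param array A [microvillar_array()] object; sets segment thickness and
#'   the number of microvilli per segment (partial trailing segments carry
#'   proportionally fewer microvilli).
#' @return A data.frame with one row per segment: `cell` (7 or 8),
#'   `segment`, `depth_um` (proximal boundary, within the tier),
#'   `rate_par`, `rate_perp`, `rate` (photons s^-1) and `n_microvilli`.
#' @export
#' @examples
#' g <- crp_geometry(10, 0.5)
#' p <- segment_absorption_profile(g, split_polarization(1e5, 0.1, 30))
#' sum(p$rate[p$cell == 7])  # equals A7 from broadband_absorption_rates()
segment_absorption_profile <- function(geometry, light,
                                       dichroic = dichroic_absorption(),
                                       model = canonical_absorptance_model(dichroic),
                                       array = microvillar_array()) {
  stopifnot(inherits(geometry, "crp_geometry"),
            inherits(light, "polarized_light"),
            inherits(array, "microvillar_array"))
  kp <- dichroic$k_par; kq <- dichroic$k_perp
  l7 <- geometry$l7; l8 <- geometry$l8
  b7 <- segment_bounds(l7, array$segment_um)
  b8 <- segment_bounds(l8, array$segment_um)
  # cumulative absorbed fraction at each boundary, per polarization component
  f7p <- diff(c(0, absorptance(model, kp * b7)))
  f7q <- diff(c(0, absorptance(model, kq * b7)))
  f8p <- diff(c(absorptance(model, kp * l7),
                absorptance(model, kp * l7 + kq * b8)))
  f8q <- diff(c(absorptance(model, kq * l7),
                absorptance(model, kq * l7 + kp * b8)))
  thick7 <- diff(c(0, b7)); thick8 <- diff(c(0, b8))
  out <- data.frame(
    cell = c(rep(7L, length(b7)), rep(8L, length(b8))),
    segment = c(seq_along(b7), seq_along(b8)),
    depth_um = c(b7, b8),
    rate_par = c(f7p * light$n_par, f8p * light$n_par),
    rate_perp = c(f7q * light$n_perp, f8q * light$n_perp),
    n_microvilli = c(thick7, thick8) * array$microvilli_per_um
  )
  out$rate <- out$rate_par + out$rate_perp
  out
}

#' Binomial transduction moments of one rhabdomere segment
#'
#' A segment with `n_m` microvilli absorbing `rate` photons s^-1 transduces,
#' per dead-time slot, at most one photon per microvillus. With Poisson
#' arrivals of intensity `nu = rate * t_d / n_m` per microvillus per slot,
#' the count over an integration time `tau` (an integer multiple of `t_d`)
#' is binomial with `n_m tau / t_d` trials and success probability
#' `1 - exp(-nu)`:
#' mean `(1 - e^-nu) n_m tau / t_d`,
#' variance `e^-nu (1 - e^-nu) n_m tau / t_d`.
#'
#' @param rate Segment absorption rate, photons s^-1 (vectorized).
#' @param n_m Number of microvilli in the segment.
#' @param dead_time_ms Microvillar dead time `t_d`, ms.
#' @param tau_ms Integration time `tau`, ms; must be an integer multiple of
#'   `t_d`.
#' @return A list with vectors `mean` and `variance` (photon counts per
#'   integration time).
#' @export
#' @examples
#' binomial_transduction_moments(1, 360, 30, 90)  # Poisson regime
binomial_transduction_moments <- function(rate, n_m, dead_time_ms = 30,
                                          tau_ms = 90) {
  stopifnot(all(rate >= 0), n_m > 0, dead_time_ms > 0)
  ratio <- tau_ms / dead_time_ms
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("`tau_ms` (", tau_ms, ") must be an integer multiple of the dead time (",
         dead_time_ms, " ms)")
  nu <- rate * (dead_time_ms / 1000) / n_m
  slots <- n_m * ratio
  p <- -expm1(-nu)   # 1 - e^-nu, accurate for small nu
  list(mean = p * slots, variance = (1 - p) * p * slots)
}

#' Transduced photon-count moments for the tiered pair
#'
#' Converts absorption rates into the mean and variance of photon counts
#' per integration time, for R7 and R8, together with the unpolarized
#' background (same total flux, `d = 0`) used for contrast normalization.
#' Without saturation transduction is lossless (`M = A`) and counts are
#' Poisson (`variance = mean = A tau`). With saturation the rhabdomere is
#' split into segments and the binomial dead-time moments
#' ([binomial_transduction_moments()]) are summed across segments;
#' background moments then also pass through the saturation model.
#'
#' @inheritParams segment_absorption_profile
#' @param tau_ms Integration time, ms.
#' @param saturation Logical.
#' @return An object of class `transduction_moments`: `mean7`, `var7`,
#'   `mean8`, `var8` and background counterparts `mean7_bg`, `var7_bg`,
#'   `mean8_bg`, `var8_bg`, all photon counts per integration time, plus
#'   `tau_ms`.
#' @export
#' @examples
#' g <- crp_geometry(100, 0.5)
#' transduce(g, split_polarization(1e3, 0.1, 0), tau_ms = 90)
transduce <- function(geometry, light, dichroic = dichroic_absorption(),
                      model = canonical_absorptance_model(dichroic),
                      array = microvillar_array(), tau_ms = 90,
                      saturation = FALSE) {
  stopifnot(inherits(geometry, "crp_geometry"),
            inherits(light, "polarized_light"))
  tau_s <- tau_ms / 1000
  bg <- split_polarization(light$total_flux, 0, light$angle)
  if (!saturation) {
    a <- broadband_absorption_rates(geometry, light, dichroic, model)
    ab <- broadband_absorption_rates(geometry, bg, dichroic, model)
    out <- list(mean7 = a$a7 * tau_s, var7 = a$a7 * tau_s,
                mean8 = a$a8 * tau_s, var8 = a$a8 * tau_s,
                mean7_bg = ab$a7 * tau_s, var7_bg = ab$a7 * tau_s,
                mean8_bg = ab$a8 * tau_s, var8_bg = ab$a8 * tau_s)
  } else {
    sat_cell <- function(prof, cell) {
      rows <- prof[prof$cell == cell, ]
      if (nrow(rows) == 0) return(list(mean = 0, variance = 0))
      mm <- mapply(function(r, n) {
        m <- binomial_transduction_moments(r, n, array$dead_time_ms, tau_ms)
        c(m$mean, m$variance)
      }, rows$rate, rows$n_microvilli)
      list(mean = sum(mm[1, ]), variance = sum(mm[2, ]))
    }
    p <- segment_absorption_profile(geometry, light, dichroic, model, array)
    pb <- segment_absorption_profile(geometry, bg, dichroic, model, array)
    s7 <- sat_cell(p, 7); s8 <- sat_cell(p, 8)
    s7b <- sat_cell(pb, 7); s8b <- sat_cell(pb, 8)
    out <- list(mean7 = s7$mean, var7 = s7$variance,
                mean8 = s8$mean, var8 = s8$variance,
                mean7_bg = s7b$mean, var7_bg = s7b$variance,
                mean8_bg = s8b$mean, var8_bg = s8b$variance)
  }
  out$tau_ms <- tau_ms
  structure(out, class = "transduction_moments")
}

#' @export
print.transduction_moments <- function(x, ...) {
  cat(sprintf("Transduced counts per %g ms:\n", x$tau_ms))
  cat(sprintf("  R7: mean %.6g, var %.6g (bg mean %.6g)\n",
              x$mean7, x$var7, x$mean7_bg))
  cat(sprintf("  R8: mean %.6g, var %.6g (bg mean %.6g)\n",
              x$mean8, x$var8, x$mean8_bg))
  invisible(x)
}
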