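# Vectorized model state over a polarization-angle grid.
#
# Returns, for each angle: transduced counts per tau for R7/R8, contrast
# signals q7/q8, opponent output Q, the contrast-noise variances
# Var(q^(tau)) and the total opponent variance sigma_Q^2. Without
# saturation counts are Poisson; with saturation the per-segment binomial
# moments are summed (the theta dependence enters only through the incident
# polarization components, so segments x angles vectorizes as a matrix).
opponent_state <- function(cfg, theta) {
  stopifnot(inherits(cfg, "opponent_config"))
  g <- cfg$geometry; dc <- cfg$dichroic; model <- cfg$model
  tau_s <- cfg$tau_ms / 1000
  cw <- cos(2 * theta * pi / 180)
  n_par <- cfg$flux * (1 + cfg$degree * cw) / 2
  n_perp <- cfg$flux - n_par
  kp <- dc$k_par; kq <- dc$k_perp

  if (!cfg$saturation) {
    fp7 <- absorptance(model, kp * g$l7)
    fq7 <- absorptance(model, kq * g$l7)
    fp8 <- absorptance(model, kp * g$l7 + kq * g$l8) - fp7
    fq8 <- absorptance(model, kq * g$l7 + kp * g$l8) - fq7
    m7 <- (fp7 * n_par + fq7 * n_perp) * tau_s
    m8 <- (fp8 * n_par + fq8 * n_perp) * tau_s
    m7_bg <- (fp7 + fq7) / 2 * cfg$flux * tau_s
    m8_bg <- (fp8 + fq8) / 2 * cfg$flux * tau_s
    v7 <- m7; v8 <- m8; v7_bg <- m7_bg; v8_bg <- m8_bg
  } else {
    prof <- segment_absorption_profile(g, split_polarization(1, 0, 0),
                                       dc, model, cfg$array)
    td <- cfg$array$dead_time_ms / 1000
    slots_per <- cfg$tau_ms / cfg$array$dead_time_ms
    cell_mom <- function(cell, n_par, n_perp) {
      rows <- prof[prof$cell == cell, ]
      if (nrow(rows) == 0)
        return(list(M = rep(0, length(n_par)), V = rep(0, length(n_par))))
      # rows$rate_par/perp are absorbed fractions of each component (unit flux)
      as_mat <- outer(rows$rate_par * 2, n_par) + outer(rows$rate_perp * 2, n_perp)
      nu <- as_mat * td / rows$n_microvilli
      p <- -expm1(-nu)
      slots <- rows$n_microvilli * slots_per
      list(M = colSums(p * slots), V = colSums((1 - p) * p * slots))
    }
    bg_par <- rep(cfg$flux / 2, length(theta))
    s7 <- cell_mom(7, n_par, n_perp); s8 <- cell_mom(8, n_par, n_perp)
    s7b <- cell_mom(7, bg_par[1], bg_par[1]); s8b <- cell_mom(8, bg_par[1], bg_par[1])
    m7 <- s7$M; v7 <- s7$V; m8 <- s8$M; v8 <- s8$V
    m7_bg <- s7b$M; v7_bg <- s7b$V; m8_bg <- s8b$M; v8_bg <- s8b$V
  }
  if (m7_bg <= 0 || m8_bg <= 0)
    stop("degenerate geometry: zero background transduction rate")
  q7 <- m7 / m7_bg; q8 <- m8 / m8_bg
  var_q7 <- v7 / m7_bg^2
  var_q8 <- v8 / m8_bg^2
  sigma_q2 <- var_q7 + var_q8 + 2 * cfg$sigma_in_sq / tau_s
  list(theta = theta, m7 = m7, m8 = m8, m7_bg = m7_bg, m8_bg = m8_bg,
       q7 = q7, q8 = q8, Q = q7 - q8,
       var_q7 = var_q7, var_q8 = var_q8, sigma_q2 = sigma_q2)
}

#' Contrast signals of R7 and R8
#'
#' Transduced counts normalized by the unpolarized background count of the
#' same total flux: `q(theta) = M(theta) / M_bg`. Without saturation this
#' equals `1 + d (PS-1)/(PS+1) cos 2(theta - theta_max)`.
#'
#' @param cfg An [opponent_config()].
#' @param theta Polarization angle(s), degrees from R7's microvillar axis.
#' @return A data.frame with columns `theta`, `q7`, `q8`.
#' @export
#' @examples
#' contrast_signal(opponent_config(), theta = c(0, 45, 90))
contrast_signal <- function(cfg, theta = seq(0, 90, by = 1)) {
  st <- opponent_state(cfg, theta)
  data.frame(theta = theta, q7 = st$q7, q8 = st$q8)
}

#' Contrast signal range of one photoreceptor
#'
#' `delta_q = q(theta_max) - q(theta_min) = 2 d (PS - 1) / (PS + 1)`.
#'
#' @param ps Polarization sensitivity, >= 1.
#' @param degree Degree of polarization in \[0, 1\].
#' @return The contrast signal range, dimensionless.
#' @export
#' @examples
#' signal_range(7.5, 0.1)
signal_range <- function(ps, degree) {
  stopifnot(all(ps >= 1), all(degree >= 0 & degree <= 1))
  2 * degree * (ps - 1) / (ps + 1)
}

#' Photon-noise-limited signal-to-noise ratio
#'
#' `SNR = delta_q * sqrt(tau * M_bg)`: the contrast signal range divided by
#' the standard deviation of Poisson contrast noise over one integration
#' time. Identical whether computed on contrast signals or on raw counts,
#' since both signal and noise are scaled by `M_bg`.
#'
#' @param delta_q Contrast signal range (see [signal_range()]).
#' @param m_bg Background transduction rate, photons s^-1, > 0.
#' @param tau_ms Integration time, ms.
#' @return Dimensionless SNR.
#' @export
snr <- function(delta_q, m_bg, tau_ms = 90) {
  stopifnot(all(m_bg > 0), tau_ms > 0)
  delta_q * sqrt(tau_ms / 1000 * m_bg)
}

#' Opponent unit output
#'
#' The opponent unit subtracts R8's contrast signal from R7's:
#' `Q(theta) = q7(theta) - q8(theta)`. Because the analysers are
#' orthogonal, Q is zero at 45 degrees (unsaturated) and its range is
#' `delta_Q = delta_q7 + delta_q8`.
#'
#' @inheritParams contrast_signal
#' @return A data.frame with columns `theta` and `Q`, with the signal range
#'   `delta_Q` (max - min over the grid) as attribute `"delta_Q"`.
#' @export
opponent_response <- function(cfg, theta = seq(0, 90, by = 0.1)) {
  st <- opponent_state(cfg, theta)
  out <- data.frame(theta = theta, Q = st$Q)
  attr(out, "delta_Q") <- max(st$Q) - min(st$Q)
  out
}

#' Opponent signal range
#'
#' `delta_Q = max_theta Q - min_theta Q`, evaluated over theta in
#' \[0, 90\] degrees (the extremes are at the grid ends).
#'
#' @inheritParams contrast_signal
#' @return The opponent signal range, dimensionless.
#' @export
opponent_signal_range <- function(cfg) {
  st <- opponent_state(cfg, c(0, 90))
  max(st$Q) - min(st$Q)
}

#' Total opponent noise variance
#'
#' Photon-noise contrast variances of R7 and R8 plus intrinsic noise from
#' each photoreceptor channel:
#' `sigma_Q^2(theta) = Var(q7) + Var(q8) + 2 sigma_in^2 / tau`. Without
#' saturation the photon terms are `M(theta) / (M_bg^2 tau)`; with
#' saturation the binomial count variances are substituted.
#'
#' @inheritParams contrast_signal
#' @return Vector of variances `sigma_Q^2(theta)`.
#' @export
opponent_noise_variance <- function(cfg, theta = seq(0, 90, by = 1)) {
  opponent_state(cfg, theta)$sigma_q2
}

#' Discriminability of polarization angle
#'
#' The just-noticeable difference `delta_theta` at angle theta is the
#' angle change that moves the opponent output by one standard deviation
#' of its noise: `|dQ/dtheta| delta_theta = sigma_Q(theta)`.
#' Discriminability is `1 / delta_theta`; it is zero where the gradient
#' vanishes (at 0 and 90 degrees).
#'
#' @inheritParams contrast_signal
#' @param dtheta Step (degrees) for the finite-difference gradient, used
#'   when saturation is on; without saturation the analytic derivative of
#'   the cosine response is used.
#' @return Vector of discriminabilities, degrees^-1.
#' @export
#' @examples
#' d <- discriminability(opponent_config(), theta = c(30, 45, 60))
discriminability <- function(cfg, theta = seq(0, 90, by = 1), dtheta = 0.01) {
  st <- opponent_state(cfg, theta)
  if (!cfg$saturation) {
    # Q(theta) = a cos 2theta with a = d (P7 + P8); recover a from Q(0)
    a <- opponent_state(cfg, 0)$Q
    grad <- abs(-2 * a * sin(2 * theta * pi / 180)) * pi / 180  # per degree
  } else {
    stp <- opponent_state(cfg, pmin(theta + dtheta, 90))
    stm <- opponent_state(cfg, pmax(theta - dtheta, 0))
    grad <- abs(stp$Q - stm$Q) /
      (pmin(theta + dtheta, 90) - pmax(theta - dtheta, 0))
  }
  grad / sqrt(st$sigma_q2)
}

#' Number of discriminable polarization angles
#'
#' Sums just-noticeable-difference steps along the path from 0 to
#' 90 degrees at constant degree of polarization, using the local
#' (angle-dependent) noise -- a Riemannian line-element sum:
#' `delta_S = sum_i |[q7(theta_i) - q7(theta_i+1)] - [q8(theta_i) -
#' q8(theta_i+1)]| / sigma_Q(theta_i)` with the jnd threshold set to one
#' noise standard deviation.
#'
#' @inheritParams contrast_signal
#' @param n Number of uniform angle steps over \[0, 90\] degrees; defaults
#'   to the config's `theta_grid_n`.
#' @return The number of discriminable angles, dimensionless.
#' @export
#' @examples
#' discriminable_angles(opponent_config(flux = 1e5))
discriminable_angles <- function(cfg, n = cfg$theta_grid_n) {
  theta <- seq(0, 90, length.out = n + 1)
  st <- opponent_state(cfg, theta)
  dq <- abs(diff(st$q7) - diff(st$q8))
  sum(dq / sqrt(st$sigma_q2[seq_len(n)]))
}

#' Mutual information between polarization angle and opponent output
#'
#' Treats the opponent unit as a Gaussian channel: given theta (uniform on
#' \[0, pi/2)), the output Q is Gaussian with mean `Q(theta)` and variance
#' `sigma_Q^2(theta)`. The mutual information
#' `I(Q; theta) = h(Q) - h(Q | theta)` is computed by trapezoidal
#' quadrature: the theta average uses `theta_n` midpoint angles and the
#' marginal density of Q is integrated on a uniform grid spanning the
#' mixture's support out to 8 standard deviations.
#'
#' @inheritParams contrast_signal
#' @param theta_n Number of theta quadrature points.
#' @param q_n Number of Q grid points.
#' @return Mutual information in bits per integration time.
#' @export
#' @examples
#' mutual_information(opponent_config(flux = 1e5))
mutual_information <- function(cfg, theta_n = 512, q_n = 2001) {
  theta <- (seq_len(theta_n) - 0.5) / theta_n * 90
  st <- opponent_state(cfg, theta)
  if (any(st$sigma_q2 <= 0))
    stop("sigma_Q = 0: mutual information requires photon or intrinsic noise")
  s <- sqrt(st$sigma_q2)
  qg <- seq(min(st$Q - 8 * s), max(st$Q + 8 * s), length.out = q_n)
  dq <- qg[2] - qg[1]
  # marginal f(Q): average of the conditional Gaussians over theta
  fq <- rep(0, q_n)
  for (i in seq_len(theta_n))
    fq <- fq + stats::dnorm(qg, st$Q[i], s[i])
  fq <- fq / theta_n
  h_q <- -sum(ifelse(fq > 0, fq * log2(fq), 0)) * dq
  h_q_given <- mean(0.5 * log2(2 * pi * exp(1) * st$sigma_q2))
  max(h_q - h_q_given, 0)
}
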