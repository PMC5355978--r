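test_that("contrast signals follow the cosine closed form", {
  cfg <- quick_cfg(degree = 0.3)
  theta <- seq(0, 90, by = 5)
  cs <- contrast_signal(cfg, theta)
  g <- cfg$geometry
  ps7 <- polarization_sensitivity(7, g, cfg$dichroic)
  ps8 <- polarization_sensitivity(8, g, cfg$dichroic)
  expect_equal(cs$q7,
               1 + 0.3 * (ps7 - 1) / (ps7 + 1) * cos(2 * theta * pi / 180),
               tolerance = 1e-9)
  expect_equal(cs$q8,
               1 - 0.3 * (ps8 - 1) / (ps8 + 1) * cos(2 * theta * pi / 180),
               tolerance = 1e-9)
  # 45 degrees looks like the unpolarized background
  expect_equal(contrast_signal(cfg, 45)$q7, 1, tolerance = 1e-12)
  cs0 <- contrast_signal(quick_cfg(degree = 0), theta)
  expect_equal(cs0$q7, rep(1, length(theta)), tolerance = 1e-12)
})

test_that("signal range formula and limits", {
  expect_equal(signal_range(1, 0.5), 0)
  expect_equal(signal_range(1e12, 0.5), 1, tolerance = 1e-10)  # -> 2d
  expect_equal(signal_range(7.5, 0.1), 0.2 * 6.5 / 8.5, tolerance = 1e-12)
})

test_that("SNR follows the square-root law and the count/contrast identity", {
  expect_equal(snr(0, 1e5), 0)
  expect_equal(snr(0.1, 4e5) / snr(0.1, 1e5), 2, tolerance = 1e-12)
  # count-domain: delta_M / sqrt(tau M_bg) with delta_M = delta_q * M_bg
  dq <- 0.153; mbg <- 2.3e4; tau <- 0.09
  count_domain <- (dq * mbg * tau) / sqrt(tau * mbg)
  expect_equal(snr(dq, mbg, 90), count_domain, tolerance = 1e-12)
})

test_that("opponent output is antisymmetric and its range adds the inputs'", {
  cfg <- quick_cfg()
  expect_equal(opponent_response(cfg, 45)$Q, 0, tolerance = 1e-12)
  g <- cfg$geometry
  ps7 <- polarization_sensitivity(7, g, cfg$dichroic)
  ps8 <- polarization_sensitivity(8, g, cfg$dichroic)
  expect_equal(opponent_signal_range(cfg),
               signal_range(ps7, 0.1) + signal_range(ps8, 0.1),
               tolerance = 1e-9)
})

test_that("opponent signal range varies little with the R8 fraction", {
  # interior of the sweep plus analytic endpoints (limit PS values)
  dq_at <- function(f8) opponent_signal_range(quick_cfg(r8_fraction = f8))
  dq <- vapply(seq(0.01, 0.99, by = 0.01), dq_at, numeric(1))
  end0 <- signal_range(polarization_sensitivity(7, crp_geometry(100, 0)), 0.1) +
    signal_range(polarization_sensitivity(8, crp_geometry(100, 0)), 0.1)
  end1 <- signal_range(polarization_sensitivity(7, crp_geometry(100, 1)), 0.1) +
    signal_range(polarization_sensitivity(8, crp_geometry(100, 1)), 0.1)
  dq <- c(end0, dq, end1)
  expect_lt(100 * (max(dq) - min(dq)) / max(dq), 7)
})

test_that("opponent noise variance decomposes into photon and intrinsic terms", {
  tau <- 0.09
  # sigma_in = 0 at the background angle: (1/M7bg + 1/M8bg)/tau in rates
  cfg <- quick_cfg(sigma_in_sq = 0)
  st <- tieredpol:::opponent_state(cfg, 45)
  expect_equal(opponent_noise_variance(cfg, 45),
               1 / st$m7_bg + 1 / st$m8_bg, tolerance = 1e-12)

  # intrinsic-noise floor as photon noise vanishes
  bright <- quick_cfg(flux = 1e12)
  expect_equal(opponent_noise_variance(bright, 45), 2 * 5e-5 / tau,
               tolerance = 1e-3)

  # additivity: R8's photon term is exactly M8/(M8bg^2)
  st2 <- tieredpol:::opponent_state(quick_cfg(), 20)
  expect_equal(st2$sigma_q2 - st2$var_q8,
               st2$var_q7 + 2 * 5e-5 / tau, tolerance = 1e-12)
})

test_that("discriminability peaks at 45 degrees and scales as sqrt(N_i)", {
  cfg <- quick_cfg()
  theta <- seq(1, 89, by = 1)
  disc <- discriminability(cfg, theta)
  expect_equal(theta[which.max(disc)], 45)
  # near-symmetric about 45 degrees: the signal gradient is exactly
  # symmetric, the angle-dependent photon noise only approximately
  expect_equal(disc, rev(disc), tolerance = 0.01)
  # gradient vanishes at the response extremes
  expect_equal(discriminability(cfg, c(0, 90)), c(0, 0), tolerance = 1e-12)

  photon <- function(ni) {
    discriminability(quick_cfg(flux = ni, sigma_in_sq = 0), 45)
  }
  expect_equal(photon(4e5) / photon(1e5), 2, tolerance = 0.01)
})

test_that("discriminable angle count behaves and converges on the grid", {
  expect_equal(discriminable_angles(quick_cfg(degree = 0)), 0,
               tolerance = 1e-12)
  expect_lt(discriminable_angles(quick_cfg(sigma_in_sq = 1e6)), 1e-3)

  s900 <- discriminable_angles(quick_cfg(), n = 900)
  s1800 <- discriminable_angles(quick_cfg(), n = 1800)
  expect_equal(s1800, s900, tolerance = 1e-3)
})

test_that("mutual information is a proper information measure", {
  expect_equal(mutual_information(quick_cfg(degree = 0)), 0,
               tolerance = 1e-6)
  mi <- vapply(c(1e4, 1e5, 1e6), function(ni) {
    mutual_information(quick_cfg(flux = ni))
  }, numeric(1))
  expect_true(all(mi >= 0))
  expect_true(all(diff(mi) > 0))  # non-decreasing in flux, no saturation

  # intrinsic-noise ceiling: flat to < 0.01 bits from 1e8 to 1e9
  expect_equal(mutual_information(quick_cfg(flux = 1e9)),
               mutual_information(quick_cfg(flux = 1e8)),
               tolerance = 0.01)

  # quadrature refinement changes the value by < 0.1%
  m1 <- mutual_information(quick_cfg(), theta_n = 512, q_n = 2001)
  m2 <- mutual_information(quick_cfg(), theta_n = 1024, q_n = 4001)
  expect_equal(m2, m1, tolerance = 1e-3)
})

test_that("mutual information quadrature matches a Monte-Carlo estimate", {
  set.seed(7)
  cfg <- quick_cfg(flux = 1e5)
  n <- 1e6
  theta <- runif(n, 0, 90)
  st <- tieredpol:::opponent_state(cfg, theta)
  q <- rnorm(n, st$Q, sqrt(st$sigma_q2))
  # binned plug-in estimator of I(Q; theta)
  tb <- cut(theta, seq(0, 90, length.out = 51))
  qb <- cut(q, seq(min(q), max(q), length.out = 101), include.lowest = TRUE)
  joint <- table(tb, qb) / n
  pt <- rowSums(joint); pq <- colSums(joint)
  outer_pq <- outer(pt, pq)
  nz <- joint > 0
  mi_mc <- sum(joint[nz] * log2(joint[nz] / outer_pq[nz]))
  expect_equal(mutual_information(cfg), mi_mc, tolerance = 0.05 / mi_mc)
})
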