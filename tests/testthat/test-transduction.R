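test_that("segment profile telescopes to the whole-photoreceptor rates", {
  g <- crp_geometry(100, 0.37)  # l8 = 37 um, l7 = 63 um
  light <- split_polarization(1e6, 0.6, 15)
  prof <- segment_absorption_profile(g, light, dc0)
  whole <- broadband_absorption_rates(g, light, dc0)
  expect_equal(sum(prof$rate[prof$cell == 7]), whole$a7,
               tolerance = 1e-9)
  expect_equal(sum(prof$rate[prof$cell == 8]), whole$a8,
               tolerance = 1e-9)

  # a single segment spanning a whole tier reproduces the tier totals
  arr1 <- microvillar_array(segment_um = 1000)
  p1 <- segment_absorption_profile(g, light, dc0, array = arr1)
  expect_equal(nrow(p1), 2)
  expect_equal(p1$rate[p1$cell == 7], whole$a7, tolerance = 1e-12)

  # zero incident flux: all segments zero
  p0 <- segment_absorption_profile(g, split_polarization(0, 0.5, 30), dc0)
  expect_true(all(p0$rate == 0))

  # partial trailing segment carries proportionally fewer microvilli
  g2 <- crp_geometry(10.5, 0)
  p2 <- segment_absorption_profile(g2, light, dc0)
  expect_equal(tail(p2$n_microvilli, 1), 0.5 * 360)
})

test_that("binomial dead-time moments match their closed forms and limits", {
  # Poisson regime: nu << 1 so mean ~ variance ~ A_s tau
  m <- binomial_transduction_moments(1, 360, 30, 90)
  expect_equal(m$mean, 0.09, tolerance = 2e-3)
  expect_equal(m$variance, 0.09, tolerance = 2e-3)

  # nu = ln 2: success probability 1/2
  n_m <- 360; td <- 30; tau <- 90
  rate <- log(2) * n_m / (td / 1000)
  m2 <- binomial_transduction_moments(rate, n_m, td, tau)
  expect_equal(m2$mean, 0.5 * n_m * tau / td, tolerance = 1e-12)
  expect_equal(m2$variance, 0.25 * n_m * tau / td, tolerance = 1e-12)

  # saturation: every slot transduces, variance collapses
  m3 <- binomial_transduction_moments(1e12, n_m, td, tau)
  expect_equal(m3$mean, n_m * tau / td, tolerance = 1e-6)
  expect_lt(m3$variance, 1e-6 * m3$mean)

  expect_error(binomial_transduction_moments(10, 360, 30, 100),
               "integer multiple")
})

test_that("binomial moments agree with Bernoulli-slot simulation", {
  set.seed(42)
  n_m <- 360; td <- 30; tau <- 90; rate <- 6000
  nu <- rate * td / 1000 / n_m
  p <- 1 - exp(-nu)
  trials <- n_m * tau / td
  nrep <- 1e5
  sims <- rbinom(nrep, trials, p)
  m <- binomial_transduction_moments(rate, n_m, td, tau)
  se_mean <- sd(sims) / sqrt(nrep)
  expect_lt(abs(mean(sims) - m$mean), 3 * se_mean)
  # variance of the sample variance ~ (mu4 - var^2)/n; 3 SE bound
  v <- var(sims)
  mu4 <- mean((sims - mean(sims))^4)
  se_var <- sqrt((mu4 - v^2) / nrep)
  expect_lt(abs(v - m$variance), 3 * se_var)
})

test_that("transduction with and without saturation behave as expected", {
  g <- crp_geometry(100, 0.5)
  light <- split_polarization(1e3, 0.1, 0)
  un <- transduce(g, light, dc0, saturation = FALSE)
  sat <- transduce(g, light, dc0, saturation = TRUE)

  # low light: saturation is negligible (< 0.5% in the mean)
  expect_equal(sat$mean7, un$mean7, tolerance = 5e-3)
  expect_equal(sat$mean8, un$mean8, tolerance = 5e-3)
  # but always a strict reduction, since 1 - e^-nu < nu
  expect_lt(sat$mean7, un$mean7)
  expect_lt(sat$mean8, un$mean8)
  # Poisson without saturation, binomial underdispersion with
  expect_equal(un$var7, un$mean7)
  expect_lt(sat$var7, sat$mean7)
  expect_gte(sat$var7, 0)

  # Poisson-limit property: per-segment nu < 1e-3 keeps moments within 0.1%
  light2 <- split_polarization(1500, 0.1, 30)  # max per-segment nu ~ 8e-4
  un2 <- transduce(g, light2, dc0, saturation = FALSE)
  sat2 <- transduce(g, light2, dc0, saturation = TRUE)
  expect_equal(sat2$mean7, un2$mean7, tolerance = 1e-3)
  expect_equal(sat2$var7, un2$var7, tolerance = 1e-3)
})

test_that("Fano factor is in (0, 1] and decreases with absorption rate", {
  rates <- c(1, 10, 100, 1e3, 1e4, 1e5)
  fano <- vapply(rates, function(r) {
    m <- binomial_transduction_moments(r, 360, 30, 90)
    m$variance / m$mean
  }, numeric(1))
  expect_true(all(fano > 0 & fano <= 1))
  expect_true(all(diff(fano) < 0))
})

test_that("moments are stable under segment refinement", {
  g <- crp_geometry(100, 0.5)
  light <- split_polarization(3e6, 0.1, 20)
  # without saturation the telescoping is exact for any segmentation
  un1 <- transduce(g, light, dc0, array = microvillar_array(segment_um = 1))
  un2 <- transduce(g, light, dc0, array = microvillar_array(segment_um = 0.5))
  expect_equal(un1$mean7, un2$mean7, tolerance = 1e-12)
  # with saturation, halving the segment changes moments by < 0.5%
  s1 <- transduce(g, light, dc0, array = microvillar_array(segment_um = 1),
                  saturation = TRUE)
  s2 <- transduce(g, light, dc0, array = microvillar_array(segment_um = 0.5),
                  saturation = TRUE)
  expect_equal(s2$mean7, s1$mean7, tolerance = 5e-3)
  expect_equal(s2$var8, s1$var8, tolerance = 5e-3)
})

test_that("saturation reduces polarization sensitivity at high flux", {
  g <- crp_geometry(100, 0.5)
  for (ni in c(1e4, 1e5, 1e6)) {
    ps_un <- polarization_sensitivity(7, g, dc0)
    ps_sat <- polarization_sensitivity(7, g, dc0, flux = ni,
                                       saturation = TRUE)
    expect_lte(ps_sat, ps_un + 1e-9)
  }
})
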