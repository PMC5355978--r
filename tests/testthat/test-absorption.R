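test_that("polarization split follows Malus components and conserves flux", {
  s <- split_polarization(100, 0, 37)
  expect_equal(c(s$n_par, s$n_perp), c(50, 50))
  s <- split_polarization(100, 1, 0)
  expect_equal(c(s$n_par, s$n_perp), c(100, 0))
  s <- split_polarization(100, 1, 30)      # cos 60 deg = 1/2
  expect_equal(c(s$n_par, s$n_perp), c(75, 25))
  expect_error(split_polarization(100, 1.2, 0), "\\[0, 1\\]")
  expect_error(split_polarization(100, -0.1, 0), "\\[0, 1\\]")
})

test_that("monochromatic absorption conserves photons per component", {
  g <- crp_geometry(100, 0.3)
  light <- split_polarization(1e5, 0.7, 25)
  a <- mono_absorption_rates(g, light, dc0)
  expect_equal(a$a7, a$a_par7 + a$a_perp7)
  expect_equal(a$a8, a$a_par8 + a$a_perp8)
  # absorbed + transmitted = incident, exactly, per polarization component
  expect_equal(a$a_par7 + a$a_par8 + a$transmitted_par, light$n_par,
               tolerance = 1e-12)
  expect_equal(a$a_perp7 + a$a_perp8 + a$transmitted_perp, light$n_perp,
               tolerance = 1e-12)

  # a zero-length R7 absorbs nothing
  a0 <- mono_absorption_rates(crp_geometry(100, 1), light, dc0)
  expect_equal(a0$a7, 0)
})

test_that("monochromatic PS reproduces the tiered-pair values", {
  g <- crp_geometry(100, 0.5)
  expect_equal(polarization_sensitivity(7, g, dc0, "monochromatic"), 7.5,
               tolerance = 1e-4)
  expect_equal(polarization_sensitivity(8, g, dc0, "monochromatic"), 13.9,
               tolerance = 5e-3)
  # vanishing R8 behind a 100 um R7: filtering amplifies PS8 beyond delta
  expect_equal(polarization_sensitivity(8, crp_geometry(100, 0), dc0,
                                        "monochromatic"),
               34, tolerance = 5e-3)
  # and PS equals the A(theta_max)/A(theta_min) ratio it is defined as
  amax <- mono_absorption_rates(g, split_polarization(1, 1, 0), dc0)
  amin <- mono_absorption_rates(g, split_polarization(1, 1, 90), dc0)
  expect_equal(amax$a7 / amin$a7,
               polarization_sensitivity(7, g, dc0, "monochromatic"),
               tolerance = 1e-12)
  expect_equal(amin$a8 / amax$a8,
               polarization_sensitivity(8, g, dc0, "monochromatic"),
               tolerance = 1e-12)
})

test_that("broadband absorption satisfies the stacked-absorptance identity", {
  g <- crp_geometry(100, 0.4)
  light <- split_polarization(1e5, 0.3, 10)
  model <- canonical_absorptance_model(dc0)
  a <- broadband_absorption_rates(g, light, dc0, model)

  kp7 <- dc0$k_par * g$l7; kq8 <- dc0$k_perp * g$l8
  expect_equal(a$a_par7 + a$a_par8,
               absorptance(model, kp7 + kq8) * light$n_par,
               tolerance = 1e-12)
  kq7 <- dc0$k_perp * g$l7; kp8 <- dc0$k_par * g$l8
  expect_equal(a$a_perp7 + a$a_perp8,
               absorptance(model, kq7 + kp8) * light$n_perp,
               tolerance = 1e-12)

  # l8 = 0 leaves nothing for R8
  a0 <- broadband_absorption_rates(crp_geometry(100, 0), light, dc0, model)
  expect_equal(a0$a8, 0)

  # unpolarized light: A7 = N_i [F_a(kappa_par7) + F_a(kappa_perp7)] / 2
  au <- broadband_absorption_rates(g, split_polarization(1e5, 0, 0), dc0,
                                   model)
  expect_equal(au$a7,
               1e5 * (absorptance(model, kp7) + absorptance(model, kq7)) / 2,
               tolerance = 1e-9)
})

test_that("broadband pipeline on a delta spectrum equals the monochromatic one", {
  delta <- make_delta_spectrum(335)
  model_fn <- exact_model_fn(delta)  # numerically 1 - e^-kappa
  g <- crp_geometry(120, 0.35)
  light <- split_polarization(1e5, 0.8, 20)
  bb <- broadband_absorption_rates(g, light, dc0, model_fn)
  mono <- mono_absorption_rates(g, light, dc0)
  for (f in c("a7", "a8", "a_par7", "a_perp8"))
    expect_equal(bb[[f]], mono[[f]], tolerance = 1e-9)
})

test_that("PS limits: vanishing length gives the dichroic ratio", {
  # broadband PS of a vanishing photoreceptor is delta, not the 0/0 of the
  # naive ratio; checked numerically just above the analytic-limit cutoff
  tiny <- crp_geometry(1e-3, 0)
  expect_equal(polarization_sensitivity(7, tiny, dc0), 10,
               tolerance = 1e-3)
  expect_equal(polarization_sensitivity(7, crp_geometry(1e-3, 1), dc0), 10,
               tolerance = 1e-3)

  # monochromatic PS8 in the l8 -> 0 limit equals delta e^{(kpar-kperp) l7}:
  # numeric evaluation at small l8 against the closed form
  for (l7 in c(10, 50, 100, 200)) {
    g <- crp_geometry(l7 + 1e-4, 1e-4 / (l7 + 1e-4))
    closed <- 10 * exp((dc0$k_par - dc0$k_perp) * l7)
    expect_equal(polarization_sensitivity(8, g, dc0, "monochromatic"),
                 closed, tolerance = 1e-3)
  }
})

test_that("birefringence phase advance is small for DRA-length rhabdomeres", {
  expect_equal(birefringence_phase(60, 0, 335), 0)
  phi <- birefringence_phase(60, 1e-3, 335)
  expect_equal(phi, 1.125, tolerance = 1e-3)
  expect_lt(phi, 1.13)
  expect_equal(birefringence_phase(120, 1e-3, 335), 2 * phi)
})
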