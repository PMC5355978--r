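# shared fixtures: default dichroic pair and a quick config builder
dc0 <- dichroic_absorption(0.0075, 10, 335)

quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(total_length = 100, r8_fraction = 0.5, degree = 0.1,
         flux = 1e5, sigma_in_sq = 5e-5, tau_ms = 90),
    list(...))
  do.call(opponent_config, args)
}

# absorptance model backed by the exact spectral integral, for
# cross-checking the broadband plumbing against first principles
exact_model_fn <- function(spectrum, template = pigment_template,
                           k_peak = 1) {
  function(kappa) exact_absorptance(spectrum, template, k_peak,
                                    kappa / k_peak)
}
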