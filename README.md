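# tieredpol

Opponent polarization coding in the tiered R7/R8 photoreceptor pair of the
fly dorsal rim area (DRA).

Flies read the sky's polarization pattern with a specialized eye region in
which photoreceptors R7 and R8 stack their rhabdomeres into one tiered
waveguide, the central rhabdomere pair (CRP). R7 sits on top and filters
the light reaching R8; their microvilli are orthogonal, so the pair acts
as two crossed polarization analysers whose signals are subtracted by an
opponent unit. Because the CRP has a fixed length, R7 and R8 compete for a
sensor resource: lengthening R7 sharpens R8's polarization sensitivity but
starves it of photons. `tieredpol` implements the full model chain needed
to analyse this trade-off and is aimed at sensory-neuroscience and
visual-ecology modellers:

* **Optics** — dichroic Beer–Lambert absorption in the tiered pair, for
  monochromatic light and for broadband UV skylight via the absorptance
  function `F_a(κ) = (1 − e^−κ)(c₀ + c₁κ + c₂κ²)` of optical depth
  `κ = k(λ_max)·l`; polarization sensitivity `PS = M(θ_max)/M(θ_min)`
  with exact analytic zero-length limits (`PS → δ`, and
  `PS₈ → δ·e^{(k∥−k⊥)l₇}` behind a filtering R7).
* **Transduction** — microvillar dead-time saturation: per-1 µm-segment
  binomial photon counts with `n_m·τ/t_d` slots and success probability
  `1 − e^−ν`, `ν = A_s·t_d/n_m`, summed over segments; Poisson in the
  low-light limit.
* **Opponent coding** — contrast signals `q = M/M_bg`, opponent output
  `Q = q₇ − q₈`, noise variance
  `Var(q₇) + Var(q₈) + 2σ_in²/τ` combining photon noise (Poisson or
  binomial) with intrinsic neural noise; two performance measures: the
  number of discriminable polarization angles (a Riemannian
  jnd-step sum over 0–90°) and the mutual information `I(Q; θ)` of the
  Gaussian channel.
* **Experiments** — sweeps and optimizations over the R8 length fraction
  and the total CRP length, the single-photoreceptor SNR length optimum,
  elongation benefits, and a reference table of R8 fractions across ten
  fly species.
* **Synthetic sky** — a UV-rich daylight spectrum generator and a 335 nm
  log-normal-type rhodopsin template so the exact spectral pipeline
  (integral absorptance + polynomial fit) runs without external data.

## Worked example

```r
library(tieredpol)

cfg <- opponent_config(total_length = 100, r8_fraction = 0.5, flux = 1e5)
cfg
#> Opponent coding configuration
#>   CRP: l = 100 um, R8 fraction = 0.5 (l7 = 50, l8 = 50)
#>   stimulus: N_i = 100000 photons/s, d = 0.1
#>   noise: sigma_in^2 = 5e-05, tau = 90 ms, saturation off

g <- crp_geometry(100, 0.5)
polarization_sensitivity(7, g)   # 8.01
polarization_sensitivity(8, g)   # 12.71
opponent_signal_range(cfg)       # 0.326
discriminable_angles(cfg)        # 6.2
mutual_information(cfg)          # 1.17 bits per 90 ms integration

optimal_length_fraction("delta_s", opponent_config(flux = 3e6),
                        refine = FALSE)
#> Optimum delta_s = 9.607 at R8 fraction = 0.33 (resolution 0.01)
#>   N_i = 3e+06 photons/s, sigma_in^2 = 5e-05, saturation off
```

Reading: with the CRP split equally at 10⁵ photons s⁻¹, broadband
self-screening pulls R7's polarization sensitivity down from its dichroic
ratio of 10 to 8.0 while R7's filtering pushes R8's up to 12.7. The
opponent unit spans a contrast range of 0.33 at 10% polarization, resolves
about 6 just-noticeable angle steps between 0° and 90°, and carries about
1.2 bits per 90 ms integration. At 30× higher flux, intrinsic noise
dominates and the optimal division shifts to a shorter R8 (fraction 0.33)
— the low-to-high-light range of optima, 0.5 down to 0.33, brackets the R8
fractions measured across fly species (`species_comparison()`).

A full study (fraction sweep, length sweep, optima, species table, JSON
manifest) can be run with `run_study()`, optionally from a YAML
configuration; `write_sky_csv()` / `read_spectrum_csv()` round-trip
spectra for the exact spectral pipeline.

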