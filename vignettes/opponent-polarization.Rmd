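---
title: "Modelling opponent polarization coding by tiered R7/R8 photoreceptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling opponent polarization coding by tiered R7/R8 photoreceptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tieredpol)
```

## The system and the question

In the dorsal rim area (DRA) of the fly eye, the photoreceptors R7 and R8
stack their rhabdomeres into a single tiered waveguide, the central
rhabdomere pair (CRP). R7 sits distally and filters the light delivered to
R8; their microvilli are orthogonal, so the pair forms two crossed
polarization analysers viewing the same patch of sky. The CRP has a fixed
length `l` (about 100 µm in the DRA), and every micrometre given to R7 is
taken from R8. This package models how that division — the R8 length
fraction `l8/l` — and the total length determine the pair's ability to
code the angle of skylight polarization, once photon noise, microvillar
saturation and intrinsic neural noise are taken into account.

## The model chain

**Optics.** Incident light of flux `N_i`, degree of polarization `d` and
angle `theta` splits into components parallel and perpendicular to R7's
microvilli, `N_par = N_i (1 + d cos 2 theta)/2` and its complement. For
monochromatic light absorption is Beer–Lambert with dichroic coefficients
`k_par > k_perp` (dichroic ratio `delta = k_par/k_perp`); R8 absorbs what
R7 transmits, with the roles of the coefficients swapped because its
microvilli are orthogonal. For broadband skylight the monochromatic
exponential is replaced by an absorptance function `F_a(kappa)` of the
optical depth `kappa = k(lambda_max) l`, represented as
`(1 - e^-kappa)(c0 + c1 kappa + c2 kappa^2)`. The canonical coefficient
set (`canonical_absorptance_model()`) makes every headline number in this
package reproducible without any spectral data; the exact spectral route
(`exact_absorptance()` + `fit_absorptance_polynomial()`) exists to
validate it against a (synthetic) sky spectrum. R8's broadband absorption
is a difference of `F_a` at stacked depths, e.g.
`[F_a(kappa_par7 + kappa_perp8) - F_a(kappa_par7)] N_par`, which accounts
exactly for the spectral filtering by R7. Polarization sensitivity (PS)
is the max/min ratio of transduction rates under fully polarized light;
self-screening lowers a photoreceptor's own PS with length, while
filtering by R7 raises R8's well above the dichroic ratio.

A numerical point we handle explicitly: as a tier length goes to zero the
PS ratio becomes 0/0. The package switches to the analytic limit below
10^-6 µm — PS of a vanishing photoreceptor equals `delta`, and a
vanishing R8 behind R7 has `PS8 = delta e^{(k_par - k_perp) l7}`
(monochromatic) or `delta F_a'(kappa_perp7)/F_a'(kappa_par7)`
(broadband). This is the behaviour the `(1 - e^-kappa)` prefactor of the
absorptance model is there to preserve.

The polynomial bracket of the canonical absorptance has a maximum: its
slope turns negative near `kappa = 9.5`, beyond the fitted range. The
model therefore carries a validity range, `kappa <= k * 1000 µm = 7.5`
(the optical depth of a 1 mm rhabdomere at the unpolarized coefficient),
and evaluating outside it is an error rather than a silent extrapolation.
All uses in the package stay below `kappa = 5.5`.

**Transduction.** Each microvillus is a transduction unit that produces
one quantum bump and is then refractory for a dead time `t_d`. Below
about 10^4 photons s^-1 transduction is taken as lossless (`M = A`,
Poisson counts). At higher fluxes the rhabdomere is divided into 1 µm
segments (distal filtering makes proximal segments absorb less), and the
count per segment over an integration time `tau` (an integer multiple of
`t_d`) is binomial: `n_m tau/t_d` trials with success probability
`1 - e^-nu`, `nu = A_s t_d / n_m`. Means and variances sum across
segments because microvilli transduce independently. The binomial model
recovers Poisson statistics when `nu` is small and saturates at
`n_m tau/t_d` counts with vanishing variance when light is intense —
saturation both compresses the signal and underdisperses the noise
(Fano factor `e^-nu`).

**Opponent coding.** Each photoreceptor's count is normalized by the
count for unpolarized light of the same intensity, giving a contrast
signal `q(theta) = M(theta)/M_bg`; the opponent unit outputs
`Q = q7 - q8` and adds intrinsic noise. Under saturation the background
is itself transduced through the saturation model — the contrast
normalization divides saturated by saturated, since transduction *is*
the saturating machinery. The opponent noise variance is
`Var(q7) + Var(q8) + 2 sigma_in^2 / tau`, with the photon terms Poisson
(`M/M_bg^2/tau`) or binomial (`Var(M^tau)/(M_bg^tau)^2`) as appropriate;
the intrinsic term enters twice because each photoreceptor channel
contributes its own contrast-referred Gaussian noise, specified as a
variance for a 1 s integration and scaled by `1/tau`.

Two performance measures follow. The **number of discriminable angles**
sums just-noticeable-difference steps from 0° to 90° with the local,
angle-dependent noise (a Riemannian line-element sum with the jnd
threshold at one noise SD); we use 900 uniform steps of 0.1°, at which
doubling the grid changes the result by well under 0.1%. The
**mutual information** treats the unit as a Gaussian channel with
angle-dependent variance and a uniform angle prior over [0, π/2):
`I = h(Q) - h(Q|theta)`, computed by trapezoidal quadrature with 512
angle midpoints and the marginal of Q on a uniform grid spanning the
mixture ± 8 SD (2001 points). Refinement checks in the test suite bound
the quadrature error below 0.1%, and a binned Monte-Carlo estimator
agrees within 0.05 bits.

## Parameters and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `F` | 2 | — | facet-lens F-ratio |
| `D_r` | 1.55 | µm | rhabdomere diameter |
| `k` | 0.0075 | µm⁻¹ | unpolarized peak absorption coefficient |
| `delta` | 10 | — | dichroic ratio `k_par/k_perp` |
| `lambda_max` | 335 | nm | rhodopsin peak wavelength |
| `l` | 100 | µm | CRP length (DRA value) |
| `d` | 0.1 | — | degree of polarization (behavioural threshold scale) |
| `t_d` | 30 | ms | microvillar dead time |
| `tau` | 90 | ms | integration time (3 dead times) |
| microvilli | 360 | µm⁻¹ | linear density (9×10⁴ per 250 µm) |
| `sigma_in_sq` | 5×10⁻⁵ | contrast² s | intrinsic noise variance (10× variant: 5×10⁻⁴) |

`k_par` and `k_perp` derive from `(k, delta)` as `2 k delta/(delta+1)`
and `2 k/(delta+1)`, so their mean and ratio are exact. Angles are in
degrees from R7's microvillar axis; R7 peaks at 0°, R8 at 90°. The
integration window is 300–412 nm on a 1 nm trapezoidal grid — far finer
than any spectral feature, and outside it the UV rhodopsin's absorption
is negligible.

## What the headline computations show

```{r headline}
g <- crp_geometry(100, 0.5)
c(ps7 = polarization_sensitivity(7, g, mode = "monochromatic"),
  ps8 = polarization_sensitivity(8, g, mode = "monochromatic"),
  ps8_limit = polarization_sensitivity(8, crp_geometry(100, 0)))
```

Filtering by a 100 µm R7 raises a vanishing R8's broadband PS to ~24
(34 for monochromatic peak-wavelength light), yet the opponent signal
range varies by under 7% across the whole division because
`(PS-1)/(PS+1)` saturates in PS. The division is decided by noise, not
signal:

```{r optima}
optimal_length_fraction("delta_s", opponent_config(flux = 1e5),
                        refine = FALSE)$argmax
optimal_length_fraction("delta_s", opponent_config(flux = 3e6),
                        refine = FALSE)$argmax
```

At low flux photon noise dominates and the optimum is an equal split; at
high flux intrinsic noise dominates and a shorter R8 (larger signal) wins,
the optimum falling to 0.33 — the range observed across fly species
(`species_comparison()`). With the intrinsic variance increased tenfold
the optimum at 10⁶ photons s⁻¹ falls further, to 0.23 in this
implementation (published value 0.25; the optimum is very broad, and on a
0.01 grid the two fractions differ by under 0.3% in the metric).
Discriminable angles and mutual information peak at the same division to
within 0.02.

## The synthetic sky and what passing tests do not show

The measured sky irradiance behind the canonical absorptance coefficients
is not redistributable, so `make_daylight_spectrum()` generates a
stand-in: a 6500 K blackbody photon spectrum modulated by `lambda^-4`
Rayleigh scattering on 300–412 nm, optionally roughened by seeded
log-normal noise. The pigment template is a log-normal-type single alpha
band: Gaussian in log-wavelength with widths 0.034 (short side) and
0.080 (long side), unity at 335 nm, decaying with a 2 nm scale beyond
the band edges. The widths were chosen once so that fitting the
polynomial to this synthetic pair tracks the canonical curve (within
~4% over `kappa` in [0, 3], fit error < 1% to 1 mm) and were not
revisited. Tests verify that the full spectral route reproduces the same
optimal length fraction as the canonical route to within 0.03 — i.e. the
conclusions are robust to the spectral stand-in — but passing them says
nothing about absolute photon fluxes under a real sky: the absolute
calibration (e.g. the incident flux on a bright day) requires measured
irradiance and is deliberately out of scope; `N_i` is a free input
everywhere.

## Numerical and design choices

* **Segmentation**: 1 µm segments; a non-integer tier length gets a
  partial trailing segment with proportionally fewer microvilli. Without
  saturation the segment sums telescope exactly; with saturation,
  halving the segment changes moments by < 0.5%.
* **`tau` as a multiple of `t_d`** is enforced only when saturation is
  on — the binomial slot construction requires it; the Poisson path does
  not.
* **Optimum searches**: 0.01-step grid over [0.01, 0.99] with first-max
  (smallest-fraction) tie-breaking, optional golden-section refinement
  to 10⁻³. Reported fractions are rounded to two decimals, lengths to
  their sweep resolution (5 µm; the saturated length optimum is reported
  on a 20 µm grid, matching the breadth of that optimum).
* **Discriminability** uses the analytic derivative of the cosine
  response without saturation and 0.01° central differences with it;
  at 0° and 90° the gradient vanishes and discriminability is reported
  as 0 rather than raising a division error.
* **Sweep sizes** used in the shipped tests and acceptance script — 99
  fraction points, 57 lengths, 900-step angle grids, 512×2001 MI
  quadrature, 10⁵–10⁶ Monte-Carlo draws — run in seconds while holding
  the convergence bounds above.

## Known limitations

* One ommatidium only: no pooling across the DRA and no downstream
  POL-neuron integration; angle and degree of polarization remain
  confounded (we fix `d`).
* Counts over a fixed window: no quantum-bump latency or shape dynamics,
  no adaptation, no time-varying stimuli.
* No waveguide mode structure, rhabdomere twist, longitudinal pupil or
  metarhodopsin photochemistry; birefringence enters only as the phase
  bound `2 pi l delta_n / lambda` showing mode mixing is negligible at
  DRA lengths.
* The published 20% gain in discriminable angles for elongation from
  100 to 240 µm at 10⁵ photons s⁻¹ is not reproduced (we obtain ~14%);
  it is mutually inconsistent with the published 16% gain for the longer
  100→300 µm extension under the same conditions, which this
  implementation does reproduce, as it does the neighbouring elongation
  figures at other fluxes.
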