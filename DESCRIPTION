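Package: tieredpol
Title: Opponent Polarization Coding in Tiered Fly Photoreceptors
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models photon absorption, transduction and opponent coding of
    skylight polarization by the tiered R7/R8 central rhabdomere pair in the
    fly dorsal rim area. Computes dichroic absorption with self-screening and
    distal filtering for monochromatic and broadband light, polarization
    sensitivity, binomial transduction-unit saturation with microvillar dead
    time, and two measures of opponent coding performance under photon and
    intrinsic noise: the number of discriminable polarization angles and the
    mutual information between polarization angle and opponent output.
    Includes parameter sweeps and resource-allocation optimizations over
    rhabdomere length fractions and total rhabdom length, and a synthetic
    UV-rich daylight spectrum generator for exercising the full spectral
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
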