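Package: leadequiv
Title: Lead-Equivalent Thickness and Areal Mass of Flexible X-Ray Shielding Composites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising lead-free flexible radiation-shielding
    composites in the diagnostic x-ray range (1-150 keV).  Vendored elemental
    photon-interaction coefficient tables with K-edge-aware log-log
    interpolation, mixture-rule attenuation for filler/polymer composites, a
    Kramers-form tungsten-anode tube spectrum model, deterministic narrow-beam
    and analog Monte Carlo broad-beam slab transmission engines, attenuation
    curve fitting with root-finding for the lead-equivalent thickness at a
    reference lead transmission, and areal-mass (kg/m^2) summaries and
    rankings across tube potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
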