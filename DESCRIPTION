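Package: mammoshield
Title: Monte Carlo Photon Transport for Contralateral-Breast Shielding
    Dosimetry in Mammography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analog Monte Carlo photon transport for evaluating
    transparent protective screens placed between the breasts during
    mammography. Builds a three-layer heterogeneous breast phantom with skin
    shells and a body block, transports monoenergetic photons through an
    axis-aligned box geometry with photoelectric absorption, Klein-Nishina
    incoherent scattering and Thomson coherent scattering under the kerma
    approximation, and tallies per-region deposited energy, planar crossing
    counts, transmission factors, lead-equivalent thicknesses and percent
    dose reductions with Monte Carlo uncertainties. Ships embedded per-element
    mass-attenuation component tables (1-150 keV) and a material library
    covering layered glandular tissue, skin, soft tissue, lead-acrylic and a
    cadmium-oxide-rich tellurite glass screen.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    knitr,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
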