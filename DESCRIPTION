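Package: pptrbruise
Title: Pulsed Photothermal Radiometry Depth Profiling of Bruised Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for depth profiling of traumatic bruises from pulsed
    photothermal radiometry (PPTR) surface-emission transients. Builds the
    radiometric kernel from the half-space heat-diffusion Green's function
    with convective surface loss and effective mid-infrared emission
    weighting, reconstructs laser-induced initial temperature-depth profiles
    by the projected nu-method (a semi-iterative regularization with a
    non-negativity constraint), and summarises reconstructions by the
    integral under the curve (IUC) and the bruise-to-healthy contrast ratio
    epsilon. Includes a synthetic two-wavelength (532 nm / 1064 nm) bruise
    study generator so the whole pipeline is testable without in vivo data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
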