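Package: oxyresp
Title: Oxygen-Limited Soil Heterotrophic Respiration from Pore-Scale Physics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic model of aerobic soil heterotrophic respiration in
    which gaseous oxygen must dissolve at water-air interfaces and diffuse
    through pore water to microbially colonized wetted pore walls. A
    volumetric-average closure yields a closed-form respiration rate as a
    function of soil saturation and temperature, with an emergent feedback
    factor that attenuates the Arrhenius temperature response. Includes
    saturation parametrizations of interfacial and wetted-wall areas and
    their fitting, calibration of the model to respiration data with
    estimation of intrinsic activation energy, scenario analyses
    (temperature-dependent optimal moisture, feedback attenuation, open soil
    surfaces, pore-scale heterogeneity), a steady-state reaction-diffusion
    pore-scale solver that verifies the closure on explicit toy geometries,
    synthetic-data generators with known ground truth, and a command-line
    workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
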