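Package: mesodiff
Title: Reaction-Diffusion Modelling of Leaf CO2 Transport and Day Respiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simplified two-dimensional reaction-diffusion model of CO2
    diffusion, Rubisco fixation and (photo)respiratory release in a leaf
    mesophyll unit cell. The model estimates day respiration (Rd) and the
    maximum Rubisco carboxylation rate (Vcmax) from combined gas-exchange and
    chlorophyll-fluorescence response curves without assuming a mesophyll
    conductance, computes the apparent mesophyll conductance and the fraction
    of (photo)respired CO2 that is reassimilated, compares the Kok, Yin and
    Laisk regression estimators of Rd against the mechanistic estimate, and
    ranks scenarios for the intracellular location of (photo)respired CO2
    release by AIC. Includes a synthetic gas-exchange data generator with
    known true parameters for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
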