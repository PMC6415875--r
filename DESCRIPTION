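Package: chamberflux
Title: CO2 Exchange Rates and Deprivation Phenotypes in Sealed Petri-Dish Plant Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers whole-culture CO2 exchange rates of in vitro plant cultures
    (e.g. Arabidopsis thaliana in sealed square Petri dishes) from chamber CO2
    concentration traces by mass-balance inversion with a Fick's-law membrane
    correction and leaf-area normalization. Includes NDIR sensor calibration
    against standard gases, seal-permeability estimation from box-decay
    experiments, exponential fitting of light/dark transition kinetics,
    power-law leaf-area growth models, a multiresponse permutation procedure
    (MRPP) for pathway-level expression testing with upper-quartile logCPM
    normalization, hue-angle kernel-density phenotyping and starch-stain
    scoring, and forward simulators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    yaml,
    rlang,
    png,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
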