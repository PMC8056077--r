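Package: seedfa
Title: Dynamic Gene-Expression-Coupled Modeling of Seed Oil Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic ordinary-differential-equation modeling of carbon and
    energy metabolism in the developing Arabidopsis embryo, driven by
    stage-resolved gene-expression profiles. Converts microarray-style mRNA
    atlases into continuous enzyme trajectories through a synthesis/degradation
    ODE with ribosome scaling and turnover classes, assembles a compartmented
    metabolic network (glycolysis, pentose-phosphate pathway, Rubisco bypass,
    plastid fatty-acid synthesis and elongation, TCA cycle, storage-product
    fluxes, maintenance), simulates storage-product accumulation over seed
    development, calibrates parameters against observed time courses, and
    predicts seed fatty-acid content changes under systematic in-silico
    single-gene knockout, knockdown and overexpression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    compiler,
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
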