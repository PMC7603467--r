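Package: pbtkcross
Title: Cross-Species Whole-Body Toxicokinetic Modelling and Parameter
    Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body physiologically based toxicokinetic (PBTK) simulation
    with a strict separation between species physiology and compound
    physicochemistry. Provides packaged mammalian species templates,
    cross-species extrapolation and allometric scaling of the
    gastrointestinal tract, tissue:plasma partition coefficients derived
    from tissue composition and ionization, a dose-normalized one-at-a-time
    parameter sensitivity analysis over model ensembles with threshold
    classification and functional grouping, synthetic species/compound
    generators, and an executable best-practice checklist for building PBTK
    models for novel species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
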