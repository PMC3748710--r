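Package: chromassay
Title: Quantification of Chromatin Assembly and Nucleosome Spacing Assays
Version: 0.1.0
Authors@R:
    person("Avery", "Lindqvist", email = "avery.lindqvist@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative readouts of in vitro chromatin
    assembly and remodeling experiments: densitometry of partial MNase
    digestion ladders and the di-/tri-nucleosome spacing index, percent
    supercoiling from DNA supercoiling assay lanes, and kinetic analyses
    (initial rates, first-order progress curves, single-exponential
    nucleosome sliding fits, Michaelis-Menten ATPase fits with basal
    correction, and relative rates with propagated uncertainty). A
    ground-truthed synthetic-data generator simulates nucleosome arrays,
    MNase digestion, gel lane profiles, supercoiling lanes, and two-step
    assembly-then-spacing kinetics so that every analysis stage can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
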