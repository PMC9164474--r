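Package: kinbayes
Title: Bayesian Kinase Inference from Phosphoproteomic Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dynamic (TMT time-course) phosphoproteomics
    of hormone-stimulated cells. Identifies regulated phosphosites by dual
    significance criteria (one-sample t-test and an empirical confidence range
    derived from per-time-point standard deviations), clusters regulated sites
    hierarchically by sequence motif (residue-class alphabet over 13-mer
    windows) and temporal pattern, and ranks candidate protein kinases per
    cluster by sequential application of Bayes' Theorem over multiple evidence
    layers (expression, phosphoacceptor preference, subcellular
    colocalization, known activity direction, and motif matching), with
    likelihoods derived from the complement of the minimum Bayes factor.
    Includes a seeded synthetic-data generator emulating every input, network
    edge export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
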