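Package: diazosip
Title: Detecting Active Diazotrophs from 15N Stable-Isotope-Probing
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying microorganisms that actively fix
    dinitrogen (diazotrophs) from 15N stable-isotope-probing (SIP)
    experiments. Implements isotope-ratio arithmetic (delta notation, atom
    percent excess, spike unmixing, acetylene-reduction equivalents), a
    per-gradient negative-binomial differential-abundance caller that
    detects OTUs enriched in the density-gradient fractions where
    isotopically labelled RNA or DNA concentrates (one-sided Wald test,
    Benjamini-Hochberg correction, abundance and profile-shape
    confirmation), gradient beta-diversity diagnostics (Morisita-Horn,
    principal coordinates), a single-cell Raman microspectroscopy
    classification harness (polynomial baseline correction, sum
    normalisation, random-forest labelling models with leave-one-strain-out
    evaluation), and seeded simulators of gradient fraction count tables,
    Raman spectra and isotope time courses with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
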