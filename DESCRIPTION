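Package: eiipScreen
Title: EIIP/AQVN Molecular Descriptors and Ellman Cholinesterase Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the average quasi-valence number (AQVN) and the
    electron-ion interaction potential (EIIP) descriptor for small
    molecules from their molecular formulas, including a formula parser,
    batch processing of compound tables and AQVN-similarity ranking.
    Also provides an analysis chain for Ellman-type cholinesterase
    inhibition assays (initial-rate extraction from microplate progress
    curves, blank correction, percent inhibition, four-parameter
    log-logistic IC50 fitting with standard errors) together with a
    Michaelis-Menten inhibition simulator that emulates a standard
    200 uL microplate protocol read at 405 nm, so the whole pipeline is
    testable against known ground truth without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, minpack.lm, jsonlite, yaml
Suggests: ChemmineOB, optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
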