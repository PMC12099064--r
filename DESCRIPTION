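Package: seqMSI
Title: Amplicon-Sequencing Microsatellite Instability Scoring and MMR
    Concordance Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Calls microsatellite instability (MSI) status from amplicon
    sequencing of a mononucleotide marker panel. Reads are converted to
    per-marker repeat-length spectra by flank-anchored repeat counting,
    per-marker deletion frequency and allelic bias features are scored with
    a naive Bayes log-likelihood-ratio classifier with Beta class
    conditionals, and samples are classified MSI-high or microsatellite
    stable with a confirmation band and median-depth quality control.
    Includes a seeded read/spectrum simulator with a PCR stutter model and
    an attenuated-instability subclass, exact contingency statistics
    (Clopper-Pearson intervals, Fisher r x c by enumeration), rank tests,
    ROC AUC, and the concordance analysis of MSI calls against mismatch
    repair protein immunohistochemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: Sequencing, Classification, SomaticMutation, Software
RoxygenNote: 7.3.3
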