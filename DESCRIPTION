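Package: secdiff
Title: Differential Analysis of Native SEC-MS Co-Fractionation Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for differential size-exclusion
    chromatography coupled mass spectrometry (SEC-MS) experiments
    comparing two conditions across replicated fraction series. Provides
    MaxQuant proteinGroups import and filtering, isoform/gene
    consolidation, replicate-presence filtering, molecular-weight
    calibration from protein standards, summed and per-fraction
    differential abundance testing with empirical-Bayes moderated
    t-statistics and left-censored missing-not-at-random imputation,
    complex-centric coelution feature detection against CORUM-style
    hypotheses with decoy-based false discovery rate control, and a
    synthetic SEC-MS data generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
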