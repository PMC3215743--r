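Package: matchedHWP
Title: Hardy-Weinberg Proportion Tests for Frequency-Matched Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests of Hardy-Weinberg proportions (HWP) in the general
    population using case-control samples whose primary-disease arms are
    frequency-matched on a secondary phenotype. Implements the extended
    likelihood-ratio test (eLRT) and the extended mixture HWP exact test
    (emHWP) over the four (trait, disease) sampling strata, the two-stratum
    baseline tests they extend, an allele-count-conditional HWP exact test,
    a synthetic frequency-matched study generator built on two logistic
    disease/trait models, and a Monte-Carlo type-I-error study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'matchedHWP-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'exact-hwp.R'
    'io.R'
    'likelihood-tests.R'
    'mixture-tests.R'
    'study-runner.R'
    'synth-data.R'
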