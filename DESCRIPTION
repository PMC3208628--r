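Package: tfcohort
Title: Transcription Factor Activity Screening and Target-Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated analysis of two-class expression data and promoter
    binding-site predictions to detect system-level transcription factor
    activity and regulator-controlled gene groups. Implements pooled SAM
    differential-expression scoring across multiple case/control comparisons,
    MATCH-style position weight matrix scanning of promoter windows, a
    per-gene target-propensity score normalized to the global binding-site
    background, a threshold-free maximum Yates-corrected chi-square screen
    for transcription factor activity with permutation-extrapolated P-values,
    and a min-P permutation test that detects gene groups whose
    differential-expression and regulator-similarity scores rise with target
    propensity, with Storey-Tibshirani q-values. Ships a synthetic-data
    generator that plants binding sites, proportional expression shifts and
    enriched gene groups so the whole pipeline can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    fgsea,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
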