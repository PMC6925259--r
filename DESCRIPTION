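Package: pdxfidelity
Title: Fidelity Assessment and Preclinical Response Analysis for Paired
    Patient-Derived Xenograft Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how faithfully patient-derived xenografts
    (PDX) recapitulate their parent primary tumors across methylation,
    copy number, mutation, and transcriptome profiles, and for scoring
    preclinical chemotherapy response in murine growth studies. Implements
    tri-state methylation classification and pairwise retention rates,
    copy-number segmentation of methylation-array total signal by circular
    binary segmentation with GC/probe-type adjustment, mutant-allele-frequency
    clonal dynamics classification and clone tracking, objective response
    calling (MCR/CR/PR/PD1/PD2) with interpolated event-free survival and
    exact log-rank tests, paired transcriptome similarity analyses, cohort
    annotation statistics including 11p15 imprinting-status classification
    and STR authentication, and a synthetic paired-cohort generator with
    known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
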