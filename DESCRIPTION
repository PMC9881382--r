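Package: sscprog
Title: Two-Stage Serum Proteomic Analysis of Progression in Preclinical
    Systemic Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage serum-proteomic progression analysis for
    preclinical systemic sclerosis cohorts. Stage one screens an aptamer-style
    protein abundance matrix (cases versus healthy controls) with a log2
    fold-change filter followed by bootstrap-aggregated out-of-bag accuracy of
    univariate median-threshold classifiers of later progression, with
    family-wise error control by the Westfall-Young step-down maxT permutation
    procedure. Stage two validates candidate markers against interval-censored
    progression times: k-nearest-neighbour imputation, Box-Cox normalisation,
    a semiparametric proportional-hazards fit for interval-censored data,
    Contal-O'Quigley optimal cutpoint dichotomisation, Turnbull nonparametric
    survival estimates per stratum, and a generalized (Finkelstein/Sun)
    logrank test. A synthetic-cohort generator reproduces the statistical
    structure of such studies so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
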