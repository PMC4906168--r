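Package: spliceSurv
Title: Survival Analysis of mRNA Isoform Variation from RNA-seq Junction
    Counts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies alternative splicing events whose exon-inclusion
    levels (PSI, per cent spliced in) are associated with patient survival
    in clinical RNA-seq cohorts. The core model couples a proportional-
    hazards model on the latent exon-inclusion level with a binomial
    measurement model for inclusion/skipping splice-junction read counts,
    integrating over the latent inclusion level so that quantification
    uncertainty at modest sequencing depth is propagated into a per-exon
    likelihood-ratio test. Includes a conventional Cox comparator fitted
    on PSI point estimates, a Gamma-Poisson cohort simulator for power and
    calibration studies, ROC and concordance-index evaluation utilities,
    Kaplan-Meier and two-means stratification helpers, and a Monte Carlo
    cross-validated survival-prediction workflow built on L1-penalized
    Cox regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    survival,
    glmnet,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: AlternativeSplicing, Survival, RNASeq, StatisticalMethod
RoxygenNote: 7.3.3
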