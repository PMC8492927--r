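Package: breedgp
Title: Multi-Breed Genomic Prediction with GBLUP and BayesC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Whole-genome regression for genomic prediction in structured
    multi-breed populations, motivated by canine orthopedic traits (hip
    dysplasia measured as the Norberg angle, cranial cruciate ligament
    rupture). Implements GBLUP with a VanRaden genomic relationship matrix
    (closed-form mixed-model solver with REML, and a Gibbs sampler in the
    kinship eigenbasis) and BayesC spike-and-slab regression via a
    compiled single-site Gibbs sampler; repeated 5-fold cross-validation
    with random, single-breed, and breed-augmented sampling strategies
    scored by Pearson correlation and AUC; trait-coding rules for angle
    traits (floor truncation, case/control binarization); marker-panel
    subsetting by gene intervals or random draws; PLINK bed/bim/fam and
    VCF input; and a Balding-Nichols multi-breed genotype simulator with
    an additive QTN trait model for power and validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
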