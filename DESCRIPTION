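Package: liporad
Title: MRI Radiomics for Discriminating Intramuscular Lipomas from
    Well-Differentiated Liposarcomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end radiomics analysis of T1-weighted MRI volumes for
    separating benign intramuscular lipomas from atypical lipomatous
    tumors / well-differentiated liposarcomas. Provides fat-referenced
    intensity normalization, a from-scratch 3D radiomic feature engine
    (first-order, shape, GLCM, GLRLM, GLSZM, GLDM and NGTDM families plus
    a tumor-to-bone distance feature), ICC(2,1) reproducibility screening,
    cross-validated LASSO logistic classification, reader-style performance
    statistics (DeLong AUC comparison, Cohen's kappa, exact binomial
    confidence intervals), and a seeded synthetic 3D phantom generator so
    the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    tools,
    utils,
    RNifti,
    pROC,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
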