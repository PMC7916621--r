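Package: cfl1bn
Title: Boolean Network Analysis of Cofilin-1 Signalling in Pancreatic Cancer
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for logical (Boolean) modelling of the cofilin-1 (CFL1)
    signalling network in pancreatic ductal adenocarcinoma. Provides a
    rule-file parser with time-delayed regulators, delay compilation into
    plain synchronous networks, synchronous simulation, exact fixed-point
    enumeration, sampled attractor search with basin-of-attraction
    estimation, exhaustive in-silico knockout/overexpression screening for
    apoptosis induction, and ROC-threshold binarization of two-class gene
    expression data. Ships the curated 33-node CFL1 model together with
    seeded synthetic-data generators and a brute-force attractor oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    xml2,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
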