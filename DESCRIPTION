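Package: structimm
Title: Structure-Based Modeling and Immunogenicity Classification of
    MHC Class I Nonamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid structural modeling of nonameric peptides in an
    HLA-A2-like binding groove by template threading and Monte-Carlo
    simulated-annealing refinement; term-decomposed energy scoring with a
    built-in approximate backend mirroring the Talaris2014 term taxonomy;
    deterministic solvent-accessible surface area (total and hydrophobic);
    structure-derived feature vectors alongside one-hot and hydropathy
    sequence baselines; and a feed-forward neural network trained by
    scaled conjugate gradients under nested 5-fold cross-validation with
    minority oversampling, for classifying peptide immunogenicity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
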