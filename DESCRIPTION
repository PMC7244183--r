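Package: taxaprop
Title: Taxon Co-Occurrence Embedding Properties for Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional "property" representations of amplicon
    sequence variants (ASVs) from their co-occurrence across microbiome
    samples with a weighted least-squares (GloVe) factorization, and projects
    arbitrary sample-by-ASV tables into the learned property space. Provides
    random-forest phenotype classification on property, PCA and normalized
    count representations with grouped, stratified train/test discipline;
    interpretation of properties through maximum-correlation permutation
    tests against metabolic pathway tables, variance-explained regression,
    Mantel tests, and a tree-backtrace association score; comparison of
    property-space structure with phylogeny via branch score and symmetric
    (Robinson-Foulds) distances under a leaf-permutation null; and a
    synthetic community generator with latent block structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    biomformat,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
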