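Package: metapept
Title: Protein 9-mer Metagenome Classification, Gene-Family Profiling and
    Count-Based Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for shotgun-metagenome community profiling from protein
    9-mers: six-frame translation and lowest-common-ancestor (LCA) indexed
    classification of reads to a consensus taxon, genus-level count tables,
    profile-match (HMMER domtblout) gene-family profiling with
    reads-per-kilobase-per-genome-equivalent (RPKG) normalization and
    average-genome-size estimation, and a count-based differential-abundance
    stack (CPM filtering, TMM normalization, quantile-adjusted conditional
    maximum likelihood negative-binomial dispersion estimation with an exact
    test, quasi-Poisson generalized linear models, Benjamini-Hochberg FDR,
    Bray-Curtis distances with PERMANOVA and multivariate dispersion
    homogeneity tests). Includes a deterministic simulator of two-treatment
    rhizosphere-like communities with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    vegan,
    withr
Config/testthat/edition: 3
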