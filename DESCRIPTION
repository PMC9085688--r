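Package: agrolandgen
Title: Landscape Genetics of Plant Populations in Agricultural Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the composition and configuration of
    agricultural landscapes to the population genetic structure of
    fragmented plant populations. Computes microsatellite diversity
    (rarefied allelic richness, expected and observed heterozygosity,
    inbreeding coefficient) and pairwise differentiation (Hedrick's
    standardized G''ST, shared-allele distance D_PS) for diploid and
    tetraploid genotypes; quantifies land use in multi-scale circular
    buffers around populations and rectangular strips between population
    pairs, including the orientation decomposition of linear landscape
    elements relative to the gene-dispersal direction; fits linear mixed
    models with a landscape-window random intercept and a maximum-likelihood
    population-effects (MLPE) correlation for pairwise data; and performs
    scale selection, collinearity reduction with principal-component
    composites, all-subsets AICc selection and full model averaging with
    term importance values and a landscape R-squared decomposition. A
    synthetic-data generator produces landscape mosaics, populations and
    genotypes with known effects so the full pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
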