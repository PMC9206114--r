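Package: recburden
Title: Recessive Rare-Variant Collapsing and Firth Burden Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case-control pipeline for detecting enrichment in rare
    recessive genotypes over a candidate gene panel: genotype- and site-level
    quality filtering of multi-sample VCF data, collapsing of qualifying
    variants into homozygous, compound-heterozygous and hemizygous
    recessive genotype calls, Firth penalized logistic burden tests with
    ancestry and sex covariates, KING-robust kinship with unrelated-subset
    selection, runs-of-homozygosity consanguinity estimation, and
    Hardy-Weinberg recessive genotype frequency estimation. Includes a
    synthetic exome-cohort generator with population structure,
    consanguinity and planted recessive genotypes, plus a built-in fixture
    reproducing the published cohort structure of a pediatric COVID-19
    pneumonia study of inborn errors of type I interferon immunity.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
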