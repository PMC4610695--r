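Package: atemp
Title: Association Tests for Multiple Phenotypes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint association testing of multiple continuous and/or ordinal
    phenotypes against a single biallelic genetic variant. Implements the
    MultiPhen proportional-odds score statistic and the equivalent generalized
    Kendall's tau statistic, together with two phenotype transformations that
    restore power when phenotypes are non-normal: the rank-based inverse normal
    transformation (ATeMP-rn) and the ordinal residual transformation
    (ATeMP-or). Includes asymptotic and permutation p-values, covariate
    adjustment, per-SNP testing from VCF or dosage-matrix genotypes, simulators
    for bivariate and high-dimensional phenotype models under normal and
    non-normal error distributions, and a Monte-Carlo harness for power and
    type-I-error evaluation over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
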