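Package: pedassoc
Title: Pedigree-Adjusted Gene-Based Sequence Association Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association tests for sequence data in pedigrees.
    Implements four case-control statistics computed over all variants in a
    gene region -- the generalized T2 test, the combined multivariate and
    collapsing (CMC) test, a functional principal component analysis (FPCA)
    score test, and the chi-square minimum test -- each made valid for
    related individuals by dividing by a kinship-derived variance correction
    factor.  Includes exact recursive kinship computation from pedigree
    files, VCF/BED-driven genome scans with Bonferroni thresholds and
    gene-set overlap summaries, replicate-based type I error and power
    estimation, and a gene-dropping simulator that generates multi-generation
    pedigrees, founder haplotypes under a mixed common/rare site-frequency
    spectrum, Mendelian transmission, and a logistic liability phenotype
    with configurable causal genes.
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
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
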