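Package: stimqtl
Title: Context-Specific QTL Mapping and Allele-Specific Co-Expression
    Analysis in Stimulated Monocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps cis quantitative trait loci for gene expression,
    transcript abundance and CpG methylation across cellular stimulation
    conditions, with permutation and conditional passes, lead-SNP
    clumping and FDR/pi1 machinery. Classifies context specificity of
    QTL effects, colocalizes association signals with approximate Bayes
    factors, runs Wald-ratio and penalised-weighted-median Mendelian
    randomization, infers methylation-expression directionality with the
    Steiger test, computes SNP feature-enrichment z-scores against
    interval annotations, discovers allele-specific co-expression QTL
    via genotype-stratified Fisher-z differential correlation, and tests
    pathway-level module differential connectivity by permutation. A
    synthetic-data generator emulates the statistical structure every
    stage assumes, so the whole pipeline is exercisable end to end
    without controlled-access cohort data.
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
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
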