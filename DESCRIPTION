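Package: hiscomsm
Title: Integrative Pathway Analysis of SNP and Metabolite Data via
    Hierarchical Structural Component Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs per-metabolite genetic risk scores ("genetic
    metabolomic scores", GMS) from SNP genotypes, either by
    clumping-and-thresholding of single-SNP association scans or by
    GBLUP-derived SNP effects with top-fraction selection, and identifies
    phenotype-associated metabolic pathways by fitting a ridge-penalized
    hierarchical structural component logistic model (GMS -> pathway
    latent variables -> binary outcome) with alternating least squares,
    cross-validated penalty selection, permutation p-values and
    Benjamini-Hochberg FDR control. Includes PLINK binary genotype I/O,
    standard variant/sample quality control, a glycemic-status
    classifier for type 2 diabetes case/control labelling, and
    synthetic-data generators for every input the pipeline consumes.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
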