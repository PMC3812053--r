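Package: snpher
Title: GREML Heritability, Genomic Partitioning, and Genetic Correlation
    for Case-Control Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of the SNP heritability of dichotomous traits with
    genetic relationship matrices (GRMs) and average-information restricted
    maximum likelihood (AI-REML), including conversion of observed-scale
    case-control estimates to the liability scale, genomic partitioning of
    heritability by chromosome, minor-allele-frequency bin, and functional
    annotation, bivariate genetic correlation between disjoint case-control
    samples, stringent SNP- and sample-level quality control, and a
    liability-threshold simulator for case-control GWAS data with
    configurable genetic architectures. Reads and writes PLINK 1 binary
    genotypes and GCTA binary GRM files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
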