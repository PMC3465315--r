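Package: esnpscan
Title: Case/Control-Aware cis and trans eSNP Mapping with
    Effective-Test Multiple-Testing Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Maps expression quantitative trait loci (eQTLs) for
    disease-risk SNPs in small case/control postmortem brain cohorts.
    Implements a 2-degree-of-freedom joint F-test of genotype and
    genotype-by-disease-status interaction on probe expression under
    dominant genotype coding, with stratified per-group effect estimates;
    microarray probe quality control (detectability and feature-flag
    filters, replicate-probe median collapse, quantile normalization,
    outlier-array screening); SNP quality control (minor allele
    frequency, Hardy-Weinberg exact test, differential missingness,
    replication and direction-of-effect filters); cis windows around risk
    loci and transcriptome-wide trans scans; and a two-step
    multiple-testing correction combining eigenvalue-based effective test
    counts with a correlation-adjusted Bonferroni threshold. A
    synthetic-data module generates LD-blocked genotypes, covariates, and
    correlated probe expression with planted group-specific eQTLs in the
    pipeline's text input formats (PED/MAP, BED, TSV).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
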