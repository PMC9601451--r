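Package: rnamodmr
Title: RNA-Modification SNP Annotation and Mendelian Randomization Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies RNA-modification-related SNPs (RNAm-SNPs) among
    genome-wide significant GWAS associations and links them to traits.
    Provides readers for GWAS, QTL and RNAm-catalogue summary tables,
    a fully specified synthetic-data generator with LD-blocked genotypes
    and a persisted truth record, permutation enrichment testing,
    instrument selection with allele harmonization and greedy LD clumping,
    two-sample Mendelian randomization estimators (IVW, weighted median,
    MR-Egger) with MR-PRESSO pleiotropy diagnostics, SMR/HEIDI summary-data
    integration of eQTL and GWAS signals, hypergeometric gene-set
    over-representation analysis, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
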