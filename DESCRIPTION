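Package: bulkseg
Title: Bulked Segregant Analysis and Sib-Based Breeding Value Pipelines for
    Pooled SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for marker discovery from pooled extreme-phenotype
    sequencing (bulked segregant analysis, BSA) in outbred livestock and
    poultry populations.  Implements per-locus pooled-bulk statistics
    (Phred quality, Euclidean distance between bulk base compositions, the
    SNP-index family and joint quality filtering), chi-square allele
    frequency contrasts between bulks with false discovery rate and
    Bonferroni control, sib-based breeding value prediction and
    extreme-group selection, genotype-trait association with Duncan mean
    separation and additive/dominance/recessive effect decomposition,
    stepwise multi-marker SNP-network regression with homozygote
    substitution effects, and relative expression comparison by the
    2^-ddCT method.  A synthetic-data generator emulates a sib-structured
    population with configurable heritability and pooled sequencing depth
    so that the whole study design can be exercised without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
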