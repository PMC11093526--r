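Package: vcpart
Title: Genome Partitioning of Genetic Variance by Multi-Component REML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions SNP heritability of quantitative traits across
    (possibly overlapping) SNP categories such as chromosomes or functional
    annotations. Builds genomic relationship matrices from PLINK genotypes,
    stores them in a packed streamable binary format, and estimates variance
    components by Fisher-scoring restricted maximum likelihood safeguarded
    with trust-region dogleg steps, using either exact or stochastic
    (probe-based) trace evaluation. Includes Haseman-Elston regression,
    MINQUE and an LD-score regression fit for statistical-efficiency
    comparisons, and a genotype/phenotype simulator with tunable linkage
    disequilibrium and full-sib family structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
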