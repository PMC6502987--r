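Package: archaicsel
Title: Enrichment of GWAS Alleles at Modern- and Archaic-Human-Specific
    Genomic Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether risk alleles from a genome-wide
    association study (GWAS) have been depleted from, or retained in, the
    modern human genome since its split from archaic hominins. Joins GWAS
    summary statistics to a catalog of modern-human-specific (MD) and
    archaic-human-specific (AD) sites, applies greedy window-based linkage
    disequilibrium pruning against a genotype reference panel, filters on
    minor allele frequency, polarizes effect directions against the
    ancestral allele (chimpanzee outgroup), bins association p-values into
    deciles, and computes fold-change enrichment scores,
    derived-risk/derived-protective ratios, and Fisher exact contrasts of
    MD versus AD sites per bin and overall. A synthetic-data generator
    with exact ground truth emulates all four inputs so the whole pipeline
    is testable without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
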