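Package: ribometh
Title: RiboMeth-Seq Scoring and Differential rRNA 2'-O-Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ribose 2'-O-methylation of ribosomal RNA
    from RiboMeth-seq read-end count profiles. Computes fractional
    methylation ("score C") over a site catalog, compares conditions with
    Student t tests and change-type classification, clusters Z-scored
    methylation matrices, annotates box C/D snoRNAs (SNORDs) and predicts
    their rRNA targets by antisense base pairing with the fifth-nucleotide
    rule, runs a simplified negative-binomial Wald test for differential
    SNORD expression, and compares codon composition and GC content of
    transcript sets. Includes a seeded synthetic-data generator with known
    ground truth for every stage and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    ggplot2,
    pheatmap,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
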