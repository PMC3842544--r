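Package: cpgdrift
Title: Culture-Associated CpG Methylation Drift Analysis for Beta-Value Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Paired differential DNA-methylation analysis on beta-value
    matrices from CpG methylation arrays, with empirical-Bayes moderated
    paired t-statistics, variance confinement and Benjamini-Hochberg
    false-discovery control; genomic-context enrichment of hyper- and
    hypomethylated sites across gene regions and CpG-island
    island/shore/shelf classes against the array background
    (exact hypergeometric tests); position-weight-matrix motif scanning and
    ChIP-seq peak co-location testing in windows around hypermethylated
    CpGs; and methylation-expression integration joining promoter
    hypermethylation to down-regulated genes. Includes a fully seeded
    synthetic-data generator (paired logit-normal beta values with planted
    condition effects, motif- and peak-bearing windows, coupled expression)
    with a ground-truth ledger, and a YAML-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
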