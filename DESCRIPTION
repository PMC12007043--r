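Package: droughtpanel
Title: Drought-Tolerance Dissection of Crop Diversity Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrated toolkit for dissecting drought tolerance in crop
    diversity panels. Combines fuzzy membership-function scoring of
    stress-relative phenotypes into a composite tolerance value, a
    kinship-corrected mixed-model association scan with LD-aware merging of
    significant SNPs into QTL intervals, windowed Weir-Cockerham Fst scans
    for selective-sweep detection between tolerant and sensitive subgroups,
    weighted co-expression network analysis (soft-threshold adjacency,
    topological overlap, module eigengenes), intersection of association and
    co-expression evidence into candidate-gene tables, and regional linkage
    disequilibrium and haplotype-group analysis. A synthetic-data generator
    with planted QTLs, sweep regions and co-expression modules supports
    power and recovery studies of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
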