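Package: pollenTE
Title: Transposable Element Expression and Marker Transmission Fitness in
    the Maize Male Gametophyte
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for transcriptome and seed-marker data from
    maize male reproductive development. Quantifies transposable element
    (TE) expression from fractionally weighted multi-mapped read counts,
    classifies TEs into near-gene / not-covered / dynamic / static
    categories against a seedling reference using a negative-binomial
    Wald test, computes a binned gene-TE neighborhood coexpression
    statistic with Kendall rank-correlation tests, assigns genes to
    mutually exclusive expression classes by FPKM, and quantifies pollen
    fitness from per-ear seed-marker transmission ratios with an
    overdispersed quasi-binomial framework. Includes seeded synthetic-data
    generators that emulate the statistical structure of each input, and
    fertilization-outcome and seed-phenotype contingency statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
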