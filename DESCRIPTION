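Package: rrnamosaic
Title: Mosaic Structure Analysis and Recombination Simulation for Chimeric rRNA Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting chimeric (mosaic) ribosomal RNA genes produced
    by horizontal gene transfer and homologous recombination. Aligns a
    recombinant gene against two candidate parents, classifies discriminating
    sites, infers the minimal-crossover parent-of-origin mosaic by dynamic
    programming, and reports recombination boundaries both as the conventional
    first-discriminating-nucleotide point and as ambiguity intervals.
    Enumerates the maximal identical shared stretches between parents that make
    crossovers possible, maps boundaries onto user-supplied structural segment
    annotations (for example accretion-model segments of 16S rRNA), and
    computes GC content separately at discriminating and consensus alignment
    columns. A mechanistic simulator of recombination in a polyploid host
    (double-crossover integration followed by iterative gene conversion,
    resolution to homogeneity, and serial-dilution enrichment) generates
    ground-truth chimera libraries for benchmarking, and a growth module
    estimates doubling times from OD600 time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
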