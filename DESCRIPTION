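Package: methredist
Title: Simulation and Analysis of DNA Methylation and Pol V Occupancy
    Redistribution Between Chromatin Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how RNA-directed DNA methylation (RdDM)
    occupancy and cytosine methylation redistribute between euchromatin and
    heterochromatin, as in linker-histone (H1) mutants of Arabidopsis.
    Provides a synthetic-data generator (multi-chromosome genomes with
    pericentromeres, short euchromatic and long heterochromatic transposable
    elements, beta-binomial methylomes per genotype, Pol V-like occupancy
    tracks with TE-edge enrichment and heterochromatic body invasion, and
    bisulfite conversion failures); methylation extraction with the
    three-context rule (CG/CHG/CHH), the consecutive-methylated-CHH
    unconverted-read filter, depth-pooled window levels and conversion-rate
    estimation; a windowed exact-test DMR caller with Homer-style interval
    merging; interval overlap statistics (Monte Carlo random-placement
    nulls, hypergeometric bin-overlap enrichment, co-occurrence similarity
    matrices with hierarchical clustering, exact rank-sum tests); ChIP
    versus input track normalization and differential-occupancy calling on
    bedGraph-style tracks; and feature metaprofiles, per-feature enrichment
    summaries and chromosomal window profiles. All functions take and
    return tidy data frames; plain-text BED, bedGraph, FASTA and
    cytosine-report formats are read and written losslessly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
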