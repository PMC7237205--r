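Package: meiohot
Title: Meiotic Recombination Hotspot Mapping and Binding Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing meiotic recombination hotspot data from
    chromatin profiling experiments: fragment-centered CUT&RUN coverage in
    genomic bins, anchor-centered signal matrices, a Poisson window
    enrichment peak caller, PRDM9 position-weight-matrix scanning with
    motif-centered hotspot filtering and F1-hybrid allele classification,
    END-seq spike-in normalization with central/flank resection
    decomposition, single-cell Spearman co-expression ranking, dual-domain
    ortholog screening with neighbor-joining paralog assignment and
    conservation profiling, and a one-set-of-sites isothermal titration
    calorimetry forward model and fit. A seeded synthetic-data generator
    produces every input modality with exported ground truth so the full
    pipeline is testable without deposited sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    minpack.lm,
    ape,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
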