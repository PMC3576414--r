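Package: clonetrace
Title: Clone Genealogies, Muller Tables, and Drift Null Tests for
    Evolve-and-Resequence Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the "fossil record" of microbial evolution
    experiments: pooled-sequencing variant tables sampled at many time points
    together with endpoint clone genotypes. Implements the variant-reporting
    filters used for pooled time-series data (minimum frequency, multi-sample
    detection, single-read masking, FASTQ read-quality filtering),
    perfect-phylogeny reconstruction of clone genealogies with midpoint dating
    of mutations and divergences, nested-lineage (Muller) frequency tables,
    a Wright-Fisher drift null model for classifying allele-frequency changes
    as selection candidates, cross-population genetic parallelism summaries
    at nucleotide, codon, and gene resolution, and a Wright-Fisher forward
    simulator (drift, beneficial mutations, optional two-ecotype negative
    frequency-dependent selection) that generates synthetic fossil records
    with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
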