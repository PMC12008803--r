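Package: pescreen
Title: Analysis of Pooled Prime-Editing Screens with Surrogate-Target Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pooled prime-editing (PE) variant
    screens that couple each pegRNA to a surrogate-target (ST) "sensor"
    sequence and barcodes on a single lentiviral cassette. Reads paired
    cassette FASTQ files, extracts and matches cassette elements with a
    mismatch tolerance, rejects recombinant cassettes, tallies pegRNA counts
    and ST editing percentages, computes pseudocounted log2 pegRNA scores
    with frequency/activity/negative-control filters, aggregates them into
    neutral-normalized variant function scores, classifies loss-of-function
    variants against an empirical normal null with Benjamini-Hochberg
    correction, sweeps ST-editing thresholds for AUC diagnostics, and
    cross-validates against endogenous-target variant counts. A synthetic
    screen generator with known per-pegRNA editing rates and per-variant
    selection effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
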