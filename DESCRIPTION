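Package: riboscope
Title: Ribosome Profiling Translatome Analysis with Ground-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for transcript-space ribosome profiling
    (Ribo-seq) analysis: per-read-length P-site offset calibration from
    start-codon metagene profiles, 3-nt periodicity and frame diagnostics,
    observed-versus-expected P-site distribution across 5'UTR/CDS/3'UTR,
    site-resolved (E/P/A) codon occupancy indices with cross-condition
    outlier detection, and transcriptome/translatome differential
    expression with translation efficiency. Includes a footprint simulator
    with known ground truth (offsets, periodicity, region weights,
    codon dwell multipliers, fold changes) so every stage is testable by
    parameter recovery. All user-facing functions take and return tidy
    data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    tools,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
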