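Package: tescape
Title: Transposable Element Landscapes, piRNA Ping-Pong Signatures, and
    Germline Silencing Pathway Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing transposable element (TE) communities
    and their germline silencing from low-coverage genomic shotgun data,
    gonadal transcriptomes and small-RNA libraries. Implements repeat-library
    redundancy clustering, mismatch-bounded ungapped read mapping and masking,
    genome-proportion and community diversity summaries (Simpson, Shannon),
    per-superfamily divergence landscapes with activity classification,
    small-RNA filtering and length/first-nucleotide statistics, putative
    piRNA selection, the ping-pong 5'-5' overlap signature with its Z-score,
    TPM aggregation by TE superfamily, sex-bias tests, and cross-species
    TE-silencing pathway expression ratios. A synthetic-data module generates
    every input with planted ground truth so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
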