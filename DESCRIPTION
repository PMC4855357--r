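Package: twintag
Title: Demultiplexing and Replicate-Aware Filtering of Double-Tagged
    Amplicon Metabarcoding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Initial processing of DNA-metabarcoding libraries built from
    amplicons carrying sample-identifying nucleotide tags at the 5' end of
    both primers and amplified in multiple PCR replicates, possibly spread
    over several sequencing pools. Reads are demultiplexed by tag
    combination, trimmed of tags and primers, and collapsed to unique
    sequences with copy numbers; unused tag combinations (tag jumping,
    primer mix-ups) are detected and diagnosed; sequences are filtered by
    reproducibility across PCR replicates, per-replicate copy number, and
    length; replicate comparability is assessed with the Renkonen
    similarity index. A seeded synthetic library generator with a full
    truth table and a truth-set benchmarking harness (TPR/FNR/FPR/TNR)
    make every stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
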