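Package: mirindel
Title: Impact of Small Insertions and Deletions on microRNA Targeting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing how small insertions and deletions
    (indels) affect microRNA targeting. Classifies indels into single-base-pair,
    repeat-expansion and other classes; profiles variant density in pre-miRNA,
    mature, seed and flanking regions and in Argonaute-crosslinking (PAR-CLIP)
    footprints; scans reference and mutant sequence windows for canonical
    miRNA seed-site motifs to call target sites disrupted or created by a
    variant; summarizes affected genes per pathway; and links miRNA-related
    indels to association-study markers through confidence-interval (Gabriel)
    linkage-disequilibrium blocks estimated from genotype panels. Includes a
    synthetic-data generator that emulates the statistical structure of the
    real inputs so every stage is testable with known ground truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
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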