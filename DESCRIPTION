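Package: srnascan
Title: Discovery of Bacterial Small Regulatory RNAs from Strand-Specific Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering small regulatory RNAs (sRNAs)
    in bacterial genomes from pre-aligned strand-specific short reads, built
    around the deep-sequencing survey design used for the cyanobacterium
    Synechocystis sp. PCC 6803. Reads are quality-filtered, categorized
    against a multi-replicon annotation (rRNA, tRNA, mRNA, misc_RNA,
    antisense, intergenic), assembled into strand-aware transcribed clusters,
    filtered by read support and length, and classified into intergenic
    sRNAs, cis-antisense RNAs, and 5'-leader candidates. Includes a
    simplified sRNA-target complementarity screen, a synthetic-data generator
    that plants sRNAs of all three classes at controlled depths for
    end-to-end validation, and tidy tibble-first interfaces with broom-style
    tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
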