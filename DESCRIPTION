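Package: wgsbakeoff
Title: Multi-Center Whole-Genome Sequencing Quality Comparison and Rare
    Loss-of-Function Variant Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing whole-genome sequencing runs of the same
    cohort across sequencing centers: k-mer-spectrum raw-read quality
    control with an explicit sample-inclusion gate, mappability and
    low-complexity genome masking, cross-center genotype concordance and
    trio Mendelian-error checks, read-depth copy-number and
    segmental-duplication calling, hard filtering of SNVs and long indels,
    and replication-based prioritization of rare loss-of-function variants
    in a case/trio cohort.  Includes a synthetic-data generator that
    emulates the full study design (paired-end reads, replicate call sets
    with controlled discordance, planted duplications and a planted causal
    variant) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
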