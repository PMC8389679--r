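Package: rsnpscan
Title: Regulatory SNP Detection by Allele-Specific Transcription Factor
    Binding Site Scanning in Promoter Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies regulatory SNPs (rSNPs) in gene promoter regions.
    Given a reference genome, a transcript annotation, a SNP catalog and a
    library of position weight matrices (PWMs), the package extracts
    strand-aware promoter windows around transcription start sites, builds
    51-bp reference and alternate flanking sequences for every promoter SNP,
    predicts transcription factor binding sites on both alleles and both
    strands with MATCH-style matrix and core similarity scores, and classifies
    each SNP's consequence on each binding site as no-effect, score-change,
    loss or gain. Results are persisted in a four-table relational schema
    (SQLite) with query, CSV-export and summary-statistics helpers, and a
    synthetic fixture generator with planted ground truth supports testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    DBI,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    RSQLite,
    rtracklayer,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
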