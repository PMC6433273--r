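Package: monosmrna
Title: Small RNA Transcriptome Analysis of LPS-Stimulated Human Monocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a small RNA-seq analysis workflow
    for LPS-stimulated human monocytes: FASTQ read QC (3' adaptor stripping,
    quality and length filtering, unique-read collapsing), exact-match
    annotation against a hierarchical small-RNA reference (miRNA hairpins,
    tRNA gene loci with 30-nt flanks, snoRNA/rRNA/Y-RNA), counts-per-million
    normalization, donor-paired differential expression with
    Benjamini-Hochberg correction, a tRNA-derived fragment (tRF) discovery
    screen with positional classification, a multi-method signature-miRNA
    decision rule, and miRNA-target expression integration. A synthetic-data
    generator produces reference sets, adaptored reads and donor-paired
    negative-binomial count matrices with the statistical structure the
    analysis assumes, so the whole pipeline runs without access to the
    original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
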