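Package: caahotspot
Title: Tumor-Only Hotspot Driver Nomination for Canine Oral Tumor Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tumor-only somatic driver-nomination pipeline for
    FFPE exome variant calls, modeled on comparative oncogenomics of canine
    acanthomatous ameloblastoma. Classifies single-nucleotide variants
    against transcript models (missense, stop-gain, splice donor/acceptor),
    transfers human cancer hotspot positions onto canine ortholog proteins
    by global alignment, applies a multi-stage evidence filter (gene list,
    known-SNP exclusion, read-depth and allele-fraction bands) with a
    targeted low-VAF hotspot rescue, infers relative copy-number profiles
    from per-target read depth with recursive binary segmentation, and
    aggregates per-case driver calls into cohort summaries. A synthetic
    FFPE tumor-exome cohort generator with full truth tracking makes every
    stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
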