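Package: vcfsift
Title: Streaming Annotation-Based Filtering of VCF Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Disk-streaming filtering of Variant Call Format (VCF) files by
    ordered chains of annotation filters. Filter directives are read from a
    plain-text filter-order file, validated against the VCF header before any
    record is read, and applied in a single pass over plain or gzip-compressed
    input with bounded memory. Supports numeric and regular-expression filters
    on INFO, FORMAT and site-level (QUAL/FILTER) annotations, zygosity
    include/exclude filters, per-sample genotype specifications for isolating
    de novo variants in multi-sample files, pass/fail output routing, export
    of passed variants to TSV, and reporting of passed variants overlapping a
    BED file of target intervals. Includes seeded generators for synthetic
    annotated VCFs (single-sample, cohort, and trio with planted de novo
    sites) and an independent brute-force filtering oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
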