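Package: cnvscan
Title: Discovery of Rare Recurrent Intergenic Copy-Number-Variant Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A genome-wide screen for rare copy-number variants (CNVs) that
    recur in unrelated cases, are absent from controls, and lie entirely
    outside annotated genes. Per-sample CNV call sets are frequency-filtered
    by reciprocal overlap against the pooled case-control cohort, intergenic
    calls are clustered into candidate regions by single-linkage interval
    overlap, and surviving regions are screened against common-variant and
    repeat-mask tracks, merged into loci, and annotated with nearest-gene
    distance, expressed-sequence evidence, a mechanism bin, and trio-based
    mode of inheritance. Includes a seeded synthetic-cohort generator with
    known ground truth for end-to-end validation, and a packaged
    transcription of a published 15-locus reference set used as a
    regression fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
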