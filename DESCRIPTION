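Package: triadomics
Title: Multi-Omics Classification of Regulatory Variation in Allotriploid Brassica Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative post-alignment analysis toolkit for interspecific
    Brassica hybrids formed by crossing allotetraploid (AACC) maternal lines
    with a diploid (AA) paternal line to yield allotriploid (AAC) F1 plants.
    Provides replicate-consistent accessible chromatin region (ACR)
    construction from ATAC-seq peaks and their classification as genic,
    proximal or distal, novel or silent, single-parent-activated, and
    transposable-element-driven; expression genetics against in-silico
    mid-parent hybrids (additive and non-additive calls, expression-level
    dominance, transgressive expression, single-parental expression, and
    subgenome dosage dependence with homolog-pair categories);
    context-specific differential methylation in fixed 200-bp bins from
    whole-genome bisulfite data with small-RNA cluster association; and a
    fully seeded synthetic allotriploid multi-omics generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    DESeq2
Config/testthat/edition: 3
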