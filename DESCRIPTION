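Package: somamotif
Title: Motif-Centered Analysis of Somatic Mutation Catalogues
Version: 0.1.0
Authors@R:
    person("somamotif", "maintainers", email = "somamotif@example.org",
           role = c("aut", "cre"))
Description: Tools for motif-centered analysis of somatic mutation
    catalogues from clonally expanded or single-cell sequenced normal
    tissues. Computes trinucleotide mutational-motif enrichment with
    Fisher's exact significance and Benjamini-Hochberg correction, and the
    enrichment-adjusted minimum estimate of mutation load (MEML)
    attributable to each mutagenic process. Includes clonal allele-fraction
    filtering, transcription-strand asymmetry tests, COSMIC ID83-style
    indel classification with homonucleotide-run and microhomology
    groupings, cross-donor structural-variant hotspot detection with
    common-fragile-site association, telomere-based estimates of mutation
    rate per cell division, and a synthetic-cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
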