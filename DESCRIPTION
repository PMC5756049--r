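Package: atchip
Title: AT-Content-Driven ChIP-seq Enrichment Analysis and Sequence Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies protein-DNA binding from ChIP-seq alignments with
    paired input and DNA-binding-domain-mutant controls, and models the
    resulting enrichment landscape as a function of local sequence
    composition. Provides fragment-length estimation from strand-split
    promoter profiles, shifted window counting, library-size-normalized
    log2 enrichment with a pseudo-count, mutant-normalized tracks,
    principal component analysis of window-level enrichments, a ladder of
    ridge-regression sequence models (k-mer, AT-stretch runs, DNA-shape
    bins) with balanced enrichment sampling and one-standard-error
    cross-validation, a spatial-proximity linear model, repeat-class
    aggregation, GC-corrected read-depth karyotyping, and a synthetic-data
    generator producing isochore-structured genomes and aligned reads with
    known binding truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
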