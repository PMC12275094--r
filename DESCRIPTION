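Package: chialoopr
Title: ChIA-PET Bridge-Linker Processing, PET Clustering and RNAPII Loop Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in situ ChIA-PET data-processing pipeline for RNA polymerase II
    chromatin-interaction libraries: detection and trimming of the biotinylated
    bridge linker in paired-end reads, tag mapping (built-in exact unique matcher
    for synthetic genomes or a SAM adapter for external aligners), PCR-duplicate
    removal at the paired-end-tag (PET) level, classification of PETs into
    self-ligation, inter-ligation and trans classes by genomic span, clustering of
    inter-ligation PETs by both-anchor overlap after 500-bp end extension, loop
    calling with PET-count, H3K27ac-anchor and anchor-distance filters,
    promoter/enhancer loop annotation, binding-coverage and raw contact-matrix
    export, and a proximity-ligation read simulator with ground truth for
    end-to-end recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
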