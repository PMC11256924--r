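Package: spliceprime
Title: Probabilistic Splicing-Status Inference for 3' Tagged-End scRNA-seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns a splicing status (spliced, unspliced or ambiguous) and a
    best gene of origin to exonic short-read scRNA-seq alignments by scoring
    putative cDNA fragments that pair each read-2 alignment with a downstream
    oligo(dT) priming site. Candidate fragments are scored under an empirical
    cDNA fragment-length distribution fitted with a cubic smoothing spline and
    a sequence-based priming-window binding-affinity classifier. The package
    builds the augmented spliced+unspliced ("spliceu") transcriptome from a
    genome and a GTF annotation, scans transcripts for adenine single
    nucleotide repeats (A-SNRs) that oligo(dT) primers can mis-prime, trains
    both model components, and ships a splice-aware paired-end read simulator
    with ground-truth labelling and ROC/AUC evaluation utilities so the whole
    method can be trained and validated on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
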