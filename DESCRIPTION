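Package: netseqr
Title: NET-Seq Pol II Pause Calling, Reproducibility and Feature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for native elongating transcript sequencing
    (NET-seq) data. Converts aligned reads to strand-specific single-nucleotide
    occupancy of nascent-RNA 3' ends, removes reverse-transcription mispriming
    artifacts, and calls single-nucleotide RNA polymerase II pause sites in
    well-expressed genes as outliers against a locally fitted negative-binomial
    background. Pause reproducibility between replicates is assessed with a
    Gaussian-copula irreproducible discovery rate (IDR) mixture model. Also
    computes region pausing indices around transcription start sites, poly(A)
    sites and splice sites, metagene profiles, splicing indices from junction
    reads, antisense transcription matrices, pause positional metrics with
    scrambled controls, and a random-forest classifier of pause loci from
    sequence, DNA-shape, positional and chromatin-track features. Includes a
    synthetic-data generator with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
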