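Package: idna
Title: Cultivar Discrimination by Exact Matching of Reduced-Representation Read Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free discrimination of plant cultivars, clones, and bud
    mutants from multiplexed reduced-representation sequencing (MIG-seq-like)
    paired-end reads. Implements the iD-NA procedure: stringent read filtering
    (zero-mismatch barcode assignment, per-base barcode quality, adapter
    screening, sliding-window quality), construction of per-sample super
    high-quality reference read sets from the intersection of PCR duplicates,
    and asymmetric exact-matching-rate similarities between comprehensive query
    read sets and reference sets, with group summaries and tabular outputs.
    Includes a synthetic amplicon cohort simulator with known cultivar
    genealogies so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pheatmap
Config/testthat/edition: 3
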