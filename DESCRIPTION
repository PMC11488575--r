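Package: ribopause
Title: Ribosome Pause Site Detection in Ribosome Profiling Data via
    Extended Isolation Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects ribosome pausing sites in ribosome profiling (Ribo-seq)
    and disome-seq data by treating pause detection as a two-dimensional
    anomaly-detection problem on normalized per-codon footprint coverage and
    normalized codon position. Transcripts are stratified into five
    expression (TPM) bins and an Extended Isolation Forest is trained per
    bin; codons whose anomaly score falls in the top score quantile are
    called pausing peaks. Includes P-site offset annotation from aligned
    read 5' ends, a seeded synthetic-translatome generator with an
    injected-pause benchmark (ROC/AUC), a position-specific z-score
    baseline, Fisher exact enrichment of codons, amino acids, codon
    optimality triplets and bicodon pairs at ribosome sites, sequence-logo
    information content and tripeptide motif clustering, tRNA adaptation
    index computation, metagene traces, and disome-seq collision geometry
    analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
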