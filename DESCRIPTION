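Package: cistromediv
Title: Cross-Species Transcription-Factor Cistrome Conservation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how transcription-factor binding landscapes
    (cistromes) diverge across related species. Assigns ChIP-seq summits to
    promoter targets with species-specific windows, classifies target genes by
    orthology-based conservation level, scores conservation of functional gene
    categories, scans sequences for degenerate (IUPAC) and position-weight-matrix
    motifs, contrasts nucleotide diversity of bound versus unbound motif
    instances with one-sided Kolmogorov-Smirnov tests, trains bag-of-k-mers
    classifiers of bound sequence, predicts differential-expression status of
    target genes with balanced-resampling random forests (with feature ablation
    and importance), and measures binding and expression concordance of
    duplicated genes. A bundled synthetic-cohort generator with planted ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    glmnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
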