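Package: psifive
Title: Protein Stability Index Estimation for N-Terminal Five-Residue Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for FACS-seq screens of N-terminal (P1-P5)
    sequence determinants of N-degron-mediated protein stability in
    Escherichia coli. Simulates NNK-mutagenized sorted libraries as per-bin
    amplicon FASTQ reads, demultiplexes and filters amplicons into per-motif
    bin-count tables, computes the Protein Stability Index (PSI) per motif,
    provides comparative analytics between protease-adaptor genotypes
    (residue-position matrices, nonparametric contrasts with Cliff's delta,
    enrichment matrices and logos, net-charge and property-group analyses),
    and trains a gradient-boosted sequence-to-stability regressor with
    additive per-feature attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
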