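Package: CellCycleSig
Title: Cell-Cycle State Signatures from FACS-Resolved Proteome Pseudotimecourses
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Periodicity screening of FACS-resolved cell-cycle proteome
    pseudotimecourses with Fisher's exact g test and Storey q-values to call
    pseudoperiodic proteins; Ward clustering and APC/C degron (KEN, D-box,
    ABBA) motif enrichment of the resulting abundance classes; construction of
    a cell-cycle-state (CCS) signature with PCA, k-NN classification and
    k-means aggregation of sorted populations; Spearman-correlation assignment
    of query proteomes to CCSs tolerant of missing values; and target/decoy
    estimation and sigma-based filtering of the MS1 feature-match (MBR) false
    discovery rate. Includes a synthetic-data generator that emulates the
    16-population x 4-biological-replicate x 2-technical-repeat design so the
    whole pipeline is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    class,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, CellCycle, TimeCourse, Classification, Clustering
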