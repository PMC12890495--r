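Package: hypergrowth
Title: Hypergraph Gene Clusters Linking Early Growth Trajectories to a
    Prehypertensive Phenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how suboptimal fetal growth followed by
    postnatal catch-up growth relates to a prehypertensive cardiometabolic
    phenotype in childhood and adolescence. Classifies birth size (SGA/AGA/LGA)
    and catch-up or catch-down status from growth percentiles, computes fetal
    and childhood weight-trajectory statistics, applies NHLBI-style
    any-criterion prehypertension phenotyping, calls differentially methylated
    points and regions and differentially expressed genes, links CpGs to genes
    by correlation, builds a shared-correlation hypergraph over candidate genes
    and extracts its central cluster, and evaluates that cluster with
    out-of-bag random forests and a Boruta shadow-feature selection loop. A
    synthetic multi-omics cohort generator with planted signal supports
    end-to-end testing without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    edgeR,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    rtracklayer,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
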