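Package: t2atlas
Title: Downstream Annotation of Lineage-Traced Fly Brain snRNA-seq Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream annotation of clustered single-nucleus
    RNA-seq atlases of the Drosophila central brain in which type-II
    neuroblast progeny carry permanent lineage-tracing transgenes
    (FLP/GFP/RFP). Provides lineage assignment from transgene positivity,
    quality-control filtering, log-normalisation and z-scaling, one-vs-rest
    Wilcoxon marker detection, per-cell fast-neurotransmitter classification
    with co-expression (UpSet) accounting, cluster-defining neuropeptide
    identification, transcription-factor combinatorial-code binarisation with
    uniqueness statistics and Jaccard ordering, sex-bias detection with
    pseudobulk differential expression, three cluster-to-neuron-type mapping
    procedures (bulk-profile correlation, enhancer-gene scoring, boolean
    marker logic), and a fully specified synthetic-data generator with known
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
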