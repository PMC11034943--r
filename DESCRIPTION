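Package: epiclone
Title: Genetic and Epigenetic Clonal Evolution in Relapsed AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for paired diagnosis/relapse acute myeloid
    leukemia (AML) samples profiled by genotyping and chromatin
    accessibility (ATAC-seq). Classifies mutation dynamics from variant
    allele frequencies and bins patients into clonal-evolution groups
    with survival comparison; builds fixed-width consensus peak sets,
    counts Tn5 cut sites, and quantifies diagnosis-to-relapse epigenetic
    similarity and differential accessibility; computes decay-weighted
    gene accessibility scores, relapse signatures, and pre-ranked gene
    set enrichment; projects single cells or pseudo-single cells onto a
    healthy hematopoietic reference by latent semantic indexing with
    k-nearest-neighbour closest-normal calls; and traces mitochondrial
    heteroplasmy clones across timepoints with a convergent epigenetic
    evolution test. A synthetic-data module generates every input with
    known ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    survival,
    igraph,
    irlba,
    FNN,
    fgsea,
    DESeq2,
    S4Vectors,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
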