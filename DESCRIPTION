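Package: fegfs
Title: Functional Gene Set Feature Extraction for Single-Cell RNA-Seq
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature extraction for single-cell RNA sequencing cell
    clustering based on Gene Ontology functional gene sets (FEGFS).
    Genes are partitioned into non-redundant GO-derived gene sets by
    hypergeometric enrichment with FDR control, SimRel semantic-similarity
    reduction of the enriched term list, and gene repetitive-rate
    reduction (coverage filtering plus threshold merging).  Each set's
    expression submatrix is reduced by cosine-kernel kernel PCA, the
    reduced blocks are concatenated into a feature matrix, and cells are
    clustered agglomeratively.  Includes the four standard external
    evaluation metrics (ARI, NMI, homogeneity, completeness), OBO/GAF/GMT
    readers and writers, a synthetic fixture generator with planted cell
    clusters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
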