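Package: atlasmatch
Title: Rank-Difference Matching of Bulk Transcriptomes Against a
    Region-Annotated Brain Expression Atlas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies the anatomical identity and developmental maturity of
    a bulk RNA-seq transcriptome by rank-difference matching against a
    region-annotated reference expression atlas. For every micro-dissected
    atlas region the per-gene absolute difference between the query's
    expression ranks and the region's averaged expression ranks is tested
    against the pooled rank differences of all other regions with a one-sided
    Wilcoxon rank-sum test; region scores are aggregated to anatomical
    structures and compared across developmental stages. Also provides the
    surrounding normalization steps (CPM, RPKM, trimmed-mean-of-M-values
    scale factors, log2, median-centering), a simplified two-group
    differential-expression test with Benjamini-Hochberg control, a synthetic
    atlas and count-data generator for end-to-end testing, score-table and
    voxel-coordinate exports, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
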