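Package: repeatdiv
Title: Repeat Clustering, Age Classification and Divergence Analysis from
    Low-Coverage Genome Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise transposable-element (TE) dynamics within
    a clonal plant lineage from low-coverage short-read sampling. Reads are
    grouped into repeat clusters with a similarity-graph method (55 %
    minimum overlap, 90 % minimum identity over the overlap), cluster read
    fractions are converted into monoploid genome occupancy, and each
    cluster's all-versus-all pairwise-identity histogram is classified into
    one of six age categories by comparing linear and quadratic fits under
    the Bayesian Information Criterion. Companion modules relate per-cluster
    genomic abundance to transcription (RPM/FPKM normalisation, linear
    regression, outlier flagging), and call qualitative differentially
    methylated positions and regions from reduced-representation bisulfite
    count tables. A seeded synthetic-data generator emulates the statistical
    structure of the inputs so every stage can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
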