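Package: catfuzz
Title: Fuzzy Clustering of Categorical Data with Co-Occurrence Value Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuzzy c-means style clustering for purely categorical data.
    Cluster centres are fuzzy centroids (per-feature weight distributions over
    category values) and the dissimilarity between two values of a feature is
    learned from the data as the average total-variation distance between their
    co-occurrence profiles against every other feature, with plain Hamming
    distance and hard mode centres available as baselines. Includes readers for
    generic categorical CSV files and the Wisconsin breast cancer dialect with
    mode imputation of missing cells, a cluster-to-class evaluation protocol
    (optimal cluster/class matching, clustering error, multi-run aggregation),
    a mixture-of-multinomials generator for synthetic categorical data, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
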