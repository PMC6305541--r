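Package: prophagescan
Title: Prophage Detection in Bacterial Genomes by Density-Based
    Clustering of Phage-Homologous Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate prophage regions in annotated bacterial
    genomes. Coding sequences with significant homology to phage proteins
    are clustered along the chromosome with density-based algorithms
    (HDBSCAN*, DBSCAN, OPTICS); candidate regions are scored with two
    reinforcing signals of horizontal transfer, G+C-content deviation in a
    sliding window and transfer-RNA genes at the region flanks, and called
    potentially conserved when most member genes derive from a single
    source phage. Includes interval-overlap benchmarking (sensitivity and
    positive predictive value against reference prophages), cluster
    validity indices (Silhouette, Dunn, Davies-Bouldin, DBCV), and a
    seeded synthetic-genome generator with implanted prophage cassettes
    for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble
Suggests:
    cluster,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
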