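Package: otuflow
Title: Amplicon Demultiplexing, OTU Construction and Windowed LCA Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact 16S rRNA amplicon processing pipeline: simultaneous
    demultiplexing and multi-criterion quality filtering of reads into
    high- and mid-quality bins, greedy centroid OTU clustering with
    read-to-OTU abundance mapping, replacement of truncated cluster
    representatives by the best full-length member read (seed extension,
    with paired-read overlap merging), identity-windowed lowest-common-
    ancestor taxonomic assignment from tabular alignment hits with
    per-rank identity depth caps, BIOM 1.0 output, and a seeded read
    simulator for validating the classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
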