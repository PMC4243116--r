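Package: apccooc
Title: Aligned Pattern Clusters and Co-Occurrence Clustering for Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers statistically significant sequence patterns in a
    protein family, groups them into Aligned Pattern Clusters (APCs) --
    gapped, wildcarded pattern matrices that represent conserved regions --
    scores how often APCs co-occur on the same sequences with the Jaccard
    index, and partitions the resulting co-occurrence graph into
    Co-occurrence Clusters by random-walk-Laplacian spectral clustering
    (with the eigengap heuristic), k-medoids, or maximum-spanning-tree
    cutting. Clusters can be validated against a reference 3D structure by
    comparing the mean distance between APC region centroids with the
    average pairwise C-alpha distance. Includes a synthetic-family
    generator with planted motifs and paired synthetic structures so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
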