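Package: phtrack
Title: Persistent-Homology Detection and Tracking of Overlapping Cell Nuclei
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects disk-like, possibly overlapping cell nuclei in
    microscopy images from the H1 persistence of binarized contour point
    clouds under the alpha filtration, places detections at circumcenters
    of the death triangles, links detections across frames by
    nearest-neighbour selection with an index-based modification mechanism,
    reduces overcounts in single images with a greedy inflated-disk cover,
    and ships seeded generators of ground-truth model series (moving disk
    cells under several noise conditions) for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deldir,
    EBImage,
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    png,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
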