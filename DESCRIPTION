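Package: cytoseg
Title: Segmentation of Overlapping Cervical Cells in Cytology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classical and clustering-based segmentation of cervical
    cytology images, from gray-level thresholding (including automatic
    threshold selection by maximum between-class variance) and edge
    operators, through pixel- and superpixel-level K-means, K-means++ and
    EM Gaussian-mixture segmentation of single cells, to a combined
    graph-cut + Voronoi + overlap-compensation pipeline that recovers
    complete cytoplasm masks for partially and heavily overlapping cells
    in multicell scenes. Ships a synthetic phantom generator that emulates
    Pap-stained single-cell and overlapping multicell benchmarks with
    exact per-cell ground truth, and the standard evaluation metrics
    (Zijdenbos similarity index, object-based false negative rate,
    pixel-based true/false positive rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
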