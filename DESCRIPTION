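Package: kdomseg
Title: Dominant-Point Polygonal Approximation and Segmentation of Touching Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recursive k-dominant-point extraction for 2-D point sets:
    polygonal approximation of convex and concave shapes driven by adaptively
    selected max-, min- and median-sum-distance measures, with closed-tag
    bookkeeping, point-set reduction and divide-and-conquer recursion.
    Includes sequence subdivision at nonsmooth (acute-angle) dominant points to
    split the merged contours of touching objects (e.g. Drosophila embryos in
    microscopy images), an end-to-end image pipeline (edge detection,
    connected components, contour closing, mask rasterization,
    intersection-over-union evaluation), and a seeded synthetic-shape
    generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
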