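Package: poremetry
Title: Pore-Size Quantification and Method Comparison for Porous Scaffold Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pore size in micro-CT style image volumes of
    porous biomaterial scaffolds and for comparing the estimators commonly used
    to report it. Provides synthetic scaffold phantom generators with known
    ground truth, adaptive-threshold binarization, 3D despeckling and
    shrink-wrap volume-of-interest extraction, a maximal-inscribed-sphere
    (local thickness) transform in 2D and 3D with a brute-force verification
    oracle, the four planar pore-size parameters (mean thickness, major
    diameter, biggest inner circle diameter, area-equivalent circle diameter),
    a seeded observer model emulating manual SEM pore measurement,
    nonparametric comparison statistics (Kruskal-Wallis with Dunn/Bonferroni
    post hoc, Mann-Whitney, quartile-based coefficient of variation), and a
    semi-quantitative quality scoring of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
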