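Package: spinecorr
Title: Dendritic Spine and PSD Morphometry with Local Rank-Correlation
    Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of dendritic-spine / postsynaptic-density
    (PSD) coupling from serial-section electron-microscopy reconstructions.
    Implements contour-based morphometry (Cavalieri volumes from closed
    traces, PSD surface areas from open and closed traces, cylindrical
    diameters section-thickness estimation), unbiased-brick density
    estimation, a sliding-window bootstrap local Spearman correlation
    procedure that detects spine-volume ranges where spine volume and PSD
    size decouple, and the group statistics comparing control and chemically
    potentiated (cLTP) spine populations (Mann-Whitney, ANCOVA on log-log
    regressions, Kruskal-Wallis with Dunn post-hoc). A synthetic population
    generator reproduces the statistical structure the analysis assumes so
    the full pipeline is testable without the original image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
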