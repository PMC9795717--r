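Package: angiocross
Title: Image-Based Morphometry of Endothelial-Mesenchymal Crosstalk in
    Microvessel-on-a-Chip Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sprouting angiogenesis and endothelial
    cell-mesenchymal stem cell (EC-MSC) crosstalk from multi-channel
    fluorescence images of microvessel-on-a-chip cultures. Provides a
    synthetic vessel-phantom generator with full ground truth (2D
    co-culture time series and 3D z-stacks); 2D analysis by kernel-window
    Pearson colocalization, vessel-edge extraction and MSC particle and
    orientation analysis; 3D surface reconstruction by marching
    tetrahedra with parent/sprout and MSC-coverage vertex tagging;
    curvature-based maturity morphometrics (surface area, enclosed
    volume, roughness, sprout range, mean curvature via the cotangent
    Laplace-Beltrami operator); the associated statistical comparisons
    (Mann-Whitney U with Bonferroni correction, two-sample
    Kolmogorov-Smirnov, two-way ANOVA with post hoc tests, linear
    regression); and a transcriptomic stage with fold-change computation,
    differentially-expressed-gene calling and clustering, and
    protein-protein-interaction confidence screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    Rcpp,
    car,
    emmeans,
    graphics,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
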