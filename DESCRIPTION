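Package: pairwise3d
Title: Pairwise 3D Surface Comparison of Fragmentary Anatomical Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pairwise comparison of 3D surface meshes of
    anatomical specimens, aimed at fragmentary material such as isolated
    fossil bones. Provides mesh input/output (OBJ, PLY, STL), landmark-based
    similarity registration and scaled iterative-closest-point (ICP) fine
    alignment with RMS convergence tracking, vertex-mask trimming and
    quadric edge-collapse decimation for resolution matching, exact
    cloud-to-cloud and cloud-to-mesh absolute distance fields with summary
    statistics, histograms and heat-map colouring, a permutation-based
    type-II analysis of variance for trial outcomes, a parametric generator
    of claw-like test specimens with controlled degradation, and a
    command-line interface tying the workflow together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
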