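Package: owhto
Title: Geometry of Posterior Tibial Slope Change in Medial Open-Wedge
    High Tibial Osteotomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates medial open-wedge high tibial osteotomy on a square
    column surrogate of the proximal tibia to quantify how the sagittal plane
    osteotomy inclination (SPOI) changes the posterior tibial slope (PTS)
    across opening-wedge correction angles. Provides exact 3D geometry of the
    wedge-opening rotation about a true lateral hinge (Rodrigues rotation and
    an equivalent closed form), a planar trigonometric endpoint model, a
    deterministic virtual-simulation grid, a calibrated Monte-Carlo emulator
    of coordinate-digitizer measurement of the slope over replicated trials,
    nonparametric (Kruskal-Wallis) analysis of the resulting tables, and STL
    export of the osteotomy fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
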