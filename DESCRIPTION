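Package: fpdconnect
Title: Automated Connector Detection and Remodelling for Fixed Partial
    Denture Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for automated, parametric redesign of the connectors of
    an n-unit fixed partial denture (FPD) given only its surface mesh.
    Reads and writes STL (binary and ASCII), frames the prosthesis in a
    labeled minimum-volume oriented bounding box, locates the connectors
    as local minima of occlusal/gingival bounding-rectangle area series
    over cross-sectional slices, and shrinks any connector's
    cross-sectional area to a target value from the occlusal, gingival,
    lingual, buccal or all (iso) directions using a Bezier-weighted
    localized vertex displacement whose scale parameter is solved by
    bisection to an area tolerance of 0.001 mm^2.  Includes isotropic
    remeshing with Hausdorff-distance quality control, planar
    cross-section metrics, a parametric synthetic-FPD generator with
    exact connector ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
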