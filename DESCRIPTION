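Package: palatemark
Title: Coarse-to-Fine Landmark Localization on Maxillary Dental Cast Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic localization of the 12 palatal gingival-margin landmarks
    (FDI teeth 16-26) on 3D maxillary dental-cast surface meshes. Implements a
    two-stage pipeline: a hierarchical set-abstraction point-cloud encoder with
    parallel distance and offset heads proposes candidate points under a
    composite distance/chamfer/separation loss; candidates are grouped by
    density-based clustering, a 6 mm geodesic patch is extracted around each
    cluster centroid, and a patch-level encoder-decoder predicts a per-point
    probability map whose argmax is the final landmark. Includes STL/PLY and
    MeshLab PickPoints I/O, canonical orientation and farthest-point sampling,
    a parametric synthetic-cast generator with analytic ground-truth landmarks,
    seeded training loops, and evaluation statistics (Euclidean error, per-axis
    MAE, success detection rates, repeatability, intraclass correlation).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
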