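Package: earlypet
Title: Optimization and Validation of Early-Phase Amyloid PET as a
    Perfusion Surrogate
Version: 0.1.0
Authors@R:
    person("IMAP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating early-phase amyloid PET (acquired during
    the first minutes after tracer injection) as a surrogate for FDG PET
    measures of neurodegeneration.  Implements early time-window
    enumeration and averaging, reference-region intensity scaling,
    Mueller-Gaertner partial-volume correction, depth-weighted projection
    of volumes onto cortical surface meshes, heat-kernel surface
    smoothing, vertex-wise within- and inter-subject correlation
    analysis with a t-to-r conversion, Friedman/Nemenyi critical
    difference ranking, permutation inference with threshold-free
    cluster enhancement and max-statistic familywise error correction,
    balanced-accuracy pattern overlap swept over a grid of statistical
    thresholds, and repeated hold-out nested cross-validation of a
    linear support vector machine on parcel-mean features.  A synthetic
    cohort generator with full ground-truth bookkeeping exercises the
    whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
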