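Package: protofil
Title: Geometry of Actin-Like Protein Filaments in Atomic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse the quaternary geometry of actin-like
    protein filaments (FtsA, MreB and relatives) from atomic coordinate
    models: inter-subunit interface detection and classification with
    local twofold (C2) symmetry testing, screw-axis decomposition of
    inter-subunit transforms into helical twist and rise, ring-closure
    prediction and symmetry expansion, filament curvature estimation by
    circle fitting, principal-axes orientation of domains and hinge
    rotation between conformers, and design of inter-subunit cysteine
    cross-links from Cbeta-Cbeta distances.  Includes single-site and
    two-step equilibrium binding-isotherm models with nonlinear
    least-squares fitting, and a synthetic-structure generator that
    places pseudo-protomers on helices, rings, arcs and antiparallel
    double filaments with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
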