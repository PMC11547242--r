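Package: ndshape
Title: Normal Density Sphere Morphometrics and Feature Prominence Scoring for Cranial Shape
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cranial dysmorphology from 3D head surface meshes.
    A head mesh is reduced to a Normal Density Sphere (NDS): a fixed-length
    vector of kernel density estimates of its unit vertex normals evaluated
    on a spherical lattice, a representation invariant to translation and
    uniform scale and equivariant to rotation. A small fully connected
    network classifies normocephalic, trigonocephalic and scaphocephalic
    shapes from the NDS; its pre-softmax output is exposed as the Feature
    Prominence (FP) severity score with per-class percentile normalization.
    Integrated-gradients attention maps are traced from density lattice
    points back through normal directions onto mesh vertices. Includes mesh
    input/output (PLY, OBJ, STL), nasion-tragus plane clipping,
    landmark-based rigid alignment, a stiffness-annealed non-rigid ICP for
    template correspondence, and a synthetic craniosynostosis head-mesh
    generator with a known severity dial for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
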