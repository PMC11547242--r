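#' @import methods
#' @importFrom stats sd approx cor rnorm runif setNames
#' @importFrom utils head tail modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib ndshape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.is_point3 <- function(p) is.numeric(p) && length(p) == 3L && all(is.finite(p))

#' TriangleMesh: a triangulated 3D surface
#'
#' Vertices are stored as an n x 3 numeric matrix in millimetres, faces as an
#' m x 3 integer matrix of 1-based vertex indices with consistent
#' (counter-clockwise, outward) winding. `topologyId` tags meshes that share a
#' common template topology so that downstream stages can verify vertex
#' correspondence; raw scans carry `NA`.
#'
#' @slot vertices numeric matrix, n x 3 (mm)
#' @slot faces integer matrix, m x 3, 1-based
#' @slot topologyId character scalar or NA
#' @export
setClass("TriangleMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  topologyId = "character"
))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L) return("vertices must be an n x 3 numeric matrix")
  if (nrow(v) == 0L) return("mesh has no vertices")
  if (!all(is.finite(v))) return("vertices contain non-finite coordinates")
  if (!is.numeric(f) || ncol(f) != 3L) return("faces must be an m x 3 integer matrix")
  if (nrow(f) == 0L) return("mesh has no faces")
  if (any(f < 1L) || any(f > nrow(v))) return("face indices out of range")
  if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
    return("degenerate faces with repeated vertex indices")
  if (length(object@topologyId) != 1L) return("topologyId must be a single string (or NA)")
  TRUE
})

#' LandmarkSet: the three anatomical landmarks defining the clipping plane
#'
#' Nasion and the left/right tragus points (mm). They must be non-collinear:
#' the plane through them is the nasion-tragus clipping plane and, ordered
#' (nasion, tragus left, tragus right), its right-handed normal points toward
#' the cranial vertex.
#'
#' @slot nasion,tragusLeft,tragusRight numeric length-3 points (mm)
#' @export
setClass("LandmarkSet", representation(
  nasion = "numeric",
  tragusLeft = "numeric",
  tragusRight = "numeric"
))

setValidity("LandmarkSet", function(object) {
  if (!.is_point3(object@nasion)) return("nasion must be a finite 3D point")
  if (!.is_point3(object@tragusLeft)) return("tragusLeft must be a finite 3D point")
  if (!.is_point3(object@tragusRight)) return("tragusRight must be a finite 3D point")
  e1 <- object@tragusLeft - object@nasion
  e2 <- object@tragusRight - object@nasion
  n <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
         e1[3L] * e2[1L] - e1[1L] * e2[3L],
         e1[1L] * e2[2L] - e1[2L] * e2[1L])
  scale <- max(sqrt(sum(e1^2)), sqrt(sum(e2^2)))
  if (scale == 0 || sqrt(sum(n^2)) <= 1e-12 * scale^2)
    return("landmarks are collinear and do not define a plane")
  TRUE
})

#' RigidTransform: a similarity transform x -> scale * R x + t
#'
#' @slot rotation 3 x 3 orthonormal matrix, det +1
#' @slot translation length-3 numeric (mm)
#' @slot scale positive scalar (1 for a pure rigid transform)
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix",
  translation = "numeric",
  scale = "numeric"
))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || !all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation is not orthonormal")
  if (abs(det(R) - 1) > 1e-9) return("rotation must have determinant +1")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite 3D vector")
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    return("scale must be a positive scalar")
  TRUE
})

#' SphereGrid: fixed evaluation lattice on the unit sphere
#'
#' The points are the locations where the normal-vector density is estimated;
#' their count fixes the network input width (4515 by default). `hash`
#' fingerprints the lattice so that descriptors from different grids are never
#' silently mixed.
#'
#' @slot points k x 3 matrix of unit vectors
#' @slot hash character fingerprint of the lattice
#' @export
setClass("SphereGrid", representation(points = "matrix", hash = "character"))

setValidity("SphereGrid", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be a k x 3 matrix")
  if (nrow(p) < 12L) return("a sphere grid needs at least 12 points")
  nrm <- sqrt(rowSums(p^2))
  if (max(abs(nrm - 1)) > 1e-12) return("grid points must be unit vectors (within 1e-12)")
  if (length(object@hash) != 1L || is.na(object@hash)) return("hash must be a single string")
  TRUE
})

#' NDSVector: the Normal Density Sphere descriptor of one mesh
#'
#' Density estimates of the mesh's unit vertex normals at each sphere-grid
#' point, together with the number of source normals n, the bandwidth h used,
#' the kernel family, and the grid fingerprint.
#'
#' @slot densities non-negative numeric vector, one value per grid point
#' @slot nSourceNormals integer, number of normals n entering the estimate
#' @slot bandwidth positive scalar h
#' @slot kernel "gaussian" or "vmf"
#' @slot gridHash fingerprint of the evaluation grid
#' @export
setClass("NDSVector", representation(
  densities = "numeric",
  nSourceNormals = "integer",
  bandwidth = "numeric",
  kernel = "character",
  gridHash = "character"
))

setValidity("NDSVector", function(object) {
  d <- object@densities
  if (length(d) < 12L) return("densities vector is implausibly short")
  if (!all(is.finite(d))) return("densities contain non-finite values")
  if (any(d < 0)) return("densities must be non-negative")
  if (object@nSourceNormals < 1L) return("nSourceNormals must be positive")
  if (!is.finite(object@bandwidth) || object@bandwidth <= 0) return("bandwidth must be positive")
  if (!object@kernel %in% c("gaussian", "vmf")) return("kernel must be 'gaussian' or 'vmf'")
  TRUE
})

#' NDSSet: a labelled collection of NDS descriptors
#'
#' Extends SummarizedExperiment: the assay `"nds"` holds one column per head
#' (rows = sphere-grid points), `colData` carries per-sample label, severity,
#' normal count and bandwidth, and `metadata` carries the grid and kernel
#' configuration shared by all columns.
#'
#' @export
setClass("NDSSet", contains = "SummarizedExperiment")

setValidity("NDSSet", function(object) {
  if (!"nds" %in% SummarizedExperiment::assayNames(object))
    return("NDSSet requires an assay named 'nds'")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'label' column")
  if (is.null(S4Vectors::metadata(object)$gridHash))
    return("metadata must record the gridHash")
  TRUE
})

#' NDSModel: the fully connected NDS classifier
#'
#' A feed-forward network with ReLU hidden layers; the default architecture is
#' 4515-256-128-64-32-3. The pre-softmax output of a class is the Feature
#' Prominence (FP) score. `trainingFP` stores, per class, the sorted FP scores
#' of that class's training samples for percentile normalization.
#'
#' @slot layerDims integer vector of layer widths (input first, classes last)
#' @slot weights,biases per-layer parameter lists
#' @slot classLabels ordered class labels
#' @slot gridHash grid fingerprint the model was trained on
#' @slot trainingFP named list of sorted per-class training FP scores
#' @slot scaling list: either empty or per-feature center/scale vectors
#' @slot seed integer RNG seed used for training
#' @slot history list of training metrics
#' @export
setClass("NDSModel", representation(
  layerDims = "integer",
  weights = "list",
  biases = "list",
  classLabels = "character",
  gridHash = "character",
  trainingFP = "list",
  scaling = "list",
  seed = "integer",
  history = "list"
))

setValidity("NDSModel", function(object) {
  L <- length(object@layerDims)
  if (L < 2L) return("need at least input and output layers")
  if (length(object@weights) != L - 1L || length(object@biases) != L - 1L)
    return("one weight and bias set per layer transition is required")
  for (l in seq_len(L - 1L)) {
    W <- object@weights[[l]]
    if (!all(dim(W) == c(object@layerDims[l], object@layerDims[l + 1L])))
      return(sprintf("weight matrix %d has dimensions incompatible with layerDims", l))
    if (length(object@biases[[l]]) != object@layerDims[l + 1L])
      return(sprintf("bias vector %d has the wrong length", l))
  }
  if (length(object@classLabels) != object@layerDims[L])
    return("class count must equal the output layer width")
  TRUE
})

#' FPResult: classification and Feature Prominence score for one head
#'
#' @slot rawFP pre-softmax network output of the scored class
#' @slot scoredClass the class whose output node was read
#' @slot probabilities softmax class probabilities
#' @slot percentile FP percentile within the scored class's training
#'   distribution, in [0, 100]; NA until normalized
#' @export
setClass("FPResult", representation(
  rawFP = "numeric",
  scoredClass = "character",
  probabilities = "numeric",
  percentile = "numeric"
))

setValidity("FPResult", function(object) {
  p <- object@probabilities
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9)
    return("probabilities must be non-negative and sum to 1")
  if (!is.na(object@percentile) &&
      (object@percentile < 0 || object@percentile > 100))
    return("percentile must lie in [0, 100]")
  TRUE
})

#' AttributionVector: integrated-gradients attributions over grid points
#'
#' @slot values signed attribution per sphere-grid point
#' @slot targetClass class whose pre-softmax output was attributed
#' @slot completenessGap |sum(values) - (F(x) - F(baseline))|
#' @slot gridHash grid fingerprint
#' @export
setClass("AttributionVector", representation(
  values = "numeric",
  targetClass = "character",
  completenessGap = "numeric",
  gridHash = "character"
))

setValidity("AttributionVector", function(object) {
  if (!all(is.finite(object@values))) return("attribution values must be finite")
  if (!is.finite(object@completenessGap)) return("completenessGap must be finite")
  TRUE
})

#' VertexAttentionMap: per-vertex attention rendering of an attribution
#'
#' @slot values one scalar per mesh vertex
#' @slot normalization "raw" or "minmax" (min-max maps to [0, 1])
#' @export
setClass("VertexAttentionMap", representation(
  values = "numeric",
  normalization = "character"
))

setValidity("VertexAttentionMap", function(object) {
  if (!object@normalization %in% c("raw", "minmax"))
    return("normalization must be 'raw' or 'minmax'")
  if (object@normalization == "minmax" &&
      length(object@values) && (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-12))
    return("minmax-normalized values must lie in [0, 1]")
  TRUE
})
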