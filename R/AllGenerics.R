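#' Accessors for ndshape objects
#'
#' `meshVertices()`, `meshFaces()` and `topologyId()` read the components of a
#' [TriangleMesh-class]; `nVertices()`/`nFaces()` count them. `gridPoints()`
#' and `gridHash()` read a [SphereGrid-class] (and `gridHash()` also works on
#' descriptors and models), and `densities()` reads an [NDSVector-class].
#'
#' @param x an ndshape object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("topologyId", function(x) standardGeneric("topologyId"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))
#' @rdname accessors
#' @export
setGeneric("gridHash", function(x) standardGeneric("gridHash"))
#' @rdname accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)
setMethod("topologyId", "TriangleMesh", function(x) x@topologyId)
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
setMethod("gridPoints", "SphereGrid", function(x) x@points)
setMethod("gridHash", "SphereGrid", function(x) x@hash)
setMethod("gridHash", "NDSVector", function(x) x@gridHash)
setMethod("gridHash", "NDSModel", function(x) x@gridHash)
setMethod("gridHash", "NDSSet", function(x) S4Vectors::metadata(x)$gridHash)
setMethod("densities", "NDSVector", function(x) x@densities)

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
setMethod("classLabels", "NDSModel", function(x) x@classLabels)

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (is.na(object@topologyId)) "" else
                sprintf(", topology '%s'", object@topologyId)))
  bb <- apply(object@vertices, 2L, range)
  cat(sprintf("  bounding box (mm): x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

setMethod("show", "SphereGrid", function(object) {
  cat(sprintf("SphereGrid: %d unit vectors (hash %s)\n",
              nrow(object@points), object@hash))
})

setMethod("show", "NDSVector", function(object) {
  cat(sprintf("NDSVector: %d densities from %d normals (%s kernel, h = %.5g)\n",
              length(object@densities), object@nSourceNormals,
              object@kernel, object@bandwidth))
  cat(sprintf("  density range [%.4g, %.4g], grid %s\n",
              min(object@densities), max(object@densities), object@gridHash))
})

setMethod("show", "NDSModel", function(object) {
  cat(sprintf("NDSModel: fully connected (%s), classes: %s\n",
              paste(object@layerDims, collapse = "-"),
              paste(object@classLabels, collapse = ", ")))
  if (length(object@history))
    cat(sprintf("  trained %d epochs, best validation accuracy %.3f\n",
                object@history$epochs, object@history$bestValAccuracy))
})

setMethod("show", "FPResult", function(object) {
  cat(sprintf("FPResult: class %s, FP = %.4f%s\n", object@scoredClass,
              object@rawFP,
              if (is.na(object@percentile)) "" else
                sprintf(" (percentile %.1f)", object@percentile)))
  cat("  probabilities:", paste(sprintf("%.3f", object@probabilities),
                                collapse = " "), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: scale %.6g, translation (%.3g, %.3g, %.3g)\n",
              object@scale, object@translation[1L], object@translation[2L],
              object@translation[3L]))
})

#' Feature Prominence score components
#'
#' @param x an [FPResult-class]
#' @return `rawFP()` the pre-softmax class output; `fpPercentile()` its
#'   per-class training percentile (NA if not normalized);
#'   `classProbabilities()` the softmax probabilities; `scoredClass()` the
#'   class label that was scored.
#' @name fp-accessors
NULL

#' @rdname fp-accessors
#' @export
setGeneric("rawFP", function(x) standardGeneric("rawFP"))
#' @rdname fp-accessors
#' @export
setGeneric("fpPercentile", function(x) standardGeneric("fpPercentile"))
#' @rdname fp-accessors
#' @export
setGeneric("classProbabilities", function(x) standardGeneric("classProbabilities"))
#' @rdname fp-accessors
#' @export
setGeneric("scoredClass", function(x) standardGeneric("scoredClass"))

setMethod("rawFP", "FPResult", function(x) x@rawFP)
setMethod("fpPercentile", "FPResult", function(x) x@percentile)
setMethod("classProbabilities", "FPResult", function(x) x@probabilities)
setMethod("scoredClass", "FPResult", function(x) x@scoredClass)

#' Attention-map values
#'
#' @param x an [AttributionVector-class] or [VertexAttentionMap-class]
#' @return numeric vector of attribution/attention values
#' @export
setGeneric("attentionValues", function(x) standardGeneric("attentionValues"))
setMethod("attentionValues", "AttributionVector", function(x) x@values)
setMethod("attentionValues", "VertexAttentionMap", function(x) x@values)
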