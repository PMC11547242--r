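## Integrated-gradients attribution over NDS inputs, traced back through
## normal directions onto mesh vertices as attention maps.

#' Integrated-gradients configuration
#'
#' @param baseline "zeros" (the IG convention), "uniform" (every grid value
#'   set to the density a uniform normal field would produce, the
#'   domain-meaningful null), or a custom numeric vector of input width
#' @param steps Riemann steps m (>= 8)
#' @param targetClass class label to attribute, or "predicted"
#' @return a configuration list
#' @export
igConfig <- function(baseline = "zeros", steps = 128L,
                     targetClass = "predicted") {
  if (is.character(baseline)) {
    baseline <- match.arg(baseline, c("zeros", "uniform"))
  } else if (!is.numeric(baseline)) {
    stop("baseline must be 'zeros', 'uniform' or a numeric vector")
  }
  steps <- as.integer(steps)
  if (steps < 8L) stop("integrated gradients needs at least 8 steps")
  list(baseline = baseline, steps = steps, targetClass = targetClass)
}

.resolve_baseline <- function(baseline, model, nds = NULL) {
  width <- model@layerDims[1L]
  if (is.numeric(baseline)) {
    if (length(baseline) != width)
      stop("custom baseline length must equal the input width ", width)
    return(as.numeric(baseline))
  }
  if (identical(baseline, "zeros")) return(numeric(width))
  # uniform-density null: normals uniform on the sphere give, per grid point,
  # E f = (1/h) * mean_kernel over the sphere ~= h / (2 sqrt(2 pi)) for the
  # Gaussian chord kernel; use the sample's own bandwidth when available
  h <- if (!is.null(nds) && is(nds, "NDSVector")) nds@bandwidth else 0.2
  rep(h / (2 * sqrt(2 * pi)), width)
}

#' Integrated gradients of the Feature Prominence output
#'
#' Attribution of the target class's pre-softmax output F_c over the NDS
#' input: IG_i = (x_i - x'_i) * (1/m) * sum_k dF_c/dx_i evaluated along the
#' straight path x' + (k/m)(x - x'), k = 1..m. The pre-softmax node — not the
#' probability — is attributed so the explanation matches the FP score. The
#' completeness gap |sum(IG) - (F(x) - F(x'))| is reported; it vanishes as m
#' grows.
#'
#' @param model a trained [NDSModel-class]
#' @param nds an [NDSVector-class] (or numeric vector of input width)
#' @param config see [igConfig()]
#' @return an [AttributionVector-class]
#' @export
integratedGradients <- function(model, nds, config = igConfig()) {
  stopifnot(is(model, "NDSModel"))
  x <- if (is(nds, "NDSVector")) {
    if (!identical(nds@gridHash, model@gridHash))
      stop("descriptor grid does not match the model's grid")
    nds@densities
  } else as.numeric(nds)
  if (length(x) != model@layerDims[1L])
    stop("input length does not match the model input width")
  bl <- .resolve_baseline(config$baseline, model, nds)
  cls <- config$targetClass
  if (identical(cls, "predicted"))
    cls <- predictNDS(model, nds)@scoredClass
  ci <- match(cls, model@classLabels)
  if (is.na(ci)) stop("unknown target class: ", cls)

  m <- config$steps
  # all m path points in one batch (after feature scaling, which is affine
  # and therefore commutes with the straight path)
  alphas <- seq_len(m) / m
  P <- outer(alphas, x - bl) + rep(bl, each = m)
  Ps <- .apply_scaling(P, model@scaling)
  G <- .mlp_input_grad(model@weights, model@biases, Ps, ci)
  if (!all(is.finite(G))) stop("non-finite gradients along the IG path")
  if (length(model@scaling)) G <- sweep(G, 2L, model@scaling$scale, "/")
  ig <- (x - bl) * colMeans(G)

  Fx <- .mlp_logits(model@weights, model@biases,
                    .apply_scaling(matrix(x, 1L), model@scaling))[1L, ci]
  Fb <- .mlp_logits(model@weights, model@biases,
                    .apply_scaling(matrix(bl, 1L), model@scaling))[1L, ci]
  new("AttributionVector", values = as.numeric(ig), targetClass = cls,
      completenessGap = abs(sum(ig) - (Fx - Fb)),
      gridHash = model@gridHash)
}

#' Project grid-point attributions onto mesh vertices
#'
#' Every vertex receives the attribution of the grid point nearest (by angle)
#' to its unit normal — the hard inverse of the normals-to-grid mapping that
#' produced the descriptor. Optionally min-max normalizes to [0, 1] for
#' rendering (red = high, blue = low); a constant attribution field has no
#' range and min-max then returns zeros.
#'
#' @param attr an [AttributionVector-class]
#' @param grid the [SphereGrid-class] the attribution lives on
#' @param normals n x 3 unit normal matrix (from [vertexNormals()])
#' @param normalization "raw" or "minmax"
#' @return a [VertexAttentionMap-class]
#' @export
projectToVertices <- function(attr, grid, normals,
                              normalization = c("raw", "minmax")) {
  normalization <- match.arg(normalization)
  stopifnot(is(attr, "AttributionVector"), is(grid, "SphereGrid"))
  if (!identical(attr@gridHash, grid@hash))
    stop("attribution grid does not match the supplied grid")
  if (length(attr@values) != nrow(grid@points))
    stop("attribution length does not match the grid size")
  if (!nrow(normals)) stop("empty normal field")
  # nearest grid point by angle == largest inner product with the normal
  dots <- normals %*% t(grid@points)
  nearest <- max.col(dots, ties.method = "first")
  vals <- attr@values[nearest]
  if (normalization == "minmax") {
    rng <- range(vals)
    if (diff(rng) <= 0) {
      warning("constant attention field; min-max normalization returns zeros")
      vals <- numeric(length(vals))
    } else {
      vals <- (vals - rng[1L]) / diff(rng)
    }
  }
  new("VertexAttentionMap", values = as.numeric(vals),
      normalization = normalization)
}

#' Average attention maps across a class
#'
#' Element-wise mean over maps that share one template topology (equal vertex
#' counts and identical normalization).
#'
#' @param maps list of [VertexAttentionMap-class]
#' @return a [VertexAttentionMap-class]
#' @export
classAverageMap <- function(maps) {
  stopifnot(length(maps) >= 1L)
  lens <- vapply(maps, function(m) length(m@values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("attention maps have mixed vertex counts (mixed topologies)")
  norms <- vapply(maps, function(m) m@normalization, character(1))
  if (length(unique(norms)) != 1L)
    stop("attention maps have mixed normalizations")
  vals <- Reduce(`+`, lapply(maps, function(m) m@values)) / length(maps)
  new("VertexAttentionMap", values = vals, normalization = norms[1L])
}

#' Export an attention map
#'
#' `writeAttentionPLY()` stores the attention as a per-vertex `quality`
#' property on a PLY copy of the mesh; `writeAttentionCSV()` writes
#' (vertex_index, value) rows.
#'
#' @param map a [VertexAttentionMap-class]
#' @param mesh the mesh the map belongs to
#' @param path output path
#' @return `path`, invisibly
#' @export
writeAttentionPLY <- function(map, mesh, path) {
  if (length(map@values) != nrow(mesh@vertices))
    stop("attention map length does not match the mesh vertex count")
  writeMesh(mesh, path, format = "ply", quality = map@values)
}

#' @rdname writeAttentionPLY
#' @export
writeAttentionCSV <- function(map, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(map@values),
                              value = map@values),
                   path, row.names = FALSE)
  invisible(path)
}
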