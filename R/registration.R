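#' RegisteredMesh: a template fitted to a target surface
#'
#' @slot mesh the deformed template (keeps the template's topologyId)
#' @slot residualRMS root-mean-square distance (mm) from the fitted vertices
#'   to the target surface
#' @slot residualHistory per-stiffness-step residual RMS
#' @slot converged logical; FALSE if any stiffness step hit its iteration cap
#' @export
setClass("RegisteredMesh", representation(
  mesh = "TriangleMesh",
  residualRMS = "numeric",
  residualHistory = "numeric",
  converged = "logical"
))

setMethod("show", "RegisteredMesh", function(object) {
  cat(sprintf("RegisteredMesh: residual RMS %.4g mm over %d vertices%s\n",
              object@residualRMS, nrow(object@mesh@vertices),
              if (object@converged) "" else " (iteration cap reached)"))
})

#' Landmark-based rigid (or similarity) alignment
#'
#' Closed-form three-point Procrustes: the least-squares transform
#' x -> scale * R x + t mapping the moving landmarks onto the fixed ones.
#' This is the pose normalization that, combined with the rotation
#' equivariance of the density descriptor, makes the pipeline invariant to
#' how a scan happens to sit in space.
#'
#' @param moving,fixed [LandmarkSet-class]s (both non-collinear)
#' @param allowScale estimate a uniform scale (similarity transform); when
#'   FALSE the scale is fixed at 1
#' @return a [RigidTransform-class]
#' @export
rigidAlign <- function(moving, fixed, allowScale = TRUE) {
  validObject(moving); validObject(fixed)
  X <- .landmark_matrix(moving)   # 3 x 3, rows = points
  Y <- .landmark_matrix(fixed)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  H <- crossprod(Xc, Yc)          # sum x_c y_c^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (allowScale) sum(diag(D) * sv$d) / sum(Xc^2) else 1
  t <- my - s * as.numeric(R %*% mx)
  new("RigidTransform", rotation = R, translation = t, scale = s)
}

#' Non-rigid ICP configuration
#'
#' Stiffness-annealed per-vertex affine registration: each annealing step
#' solves a sparse least-squares problem balancing closest-point attraction
#' to the target against smoothness of neighbouring vertices' affine
#' transforms, with the stiffness weight decreasing over the schedule.
#'
#' @param stiffness strictly decreasing positive stiffness weights
#' @param maxIter iteration cap per stiffness step
#' @param tol convergence tolerance (mm) on the maximum vertex displacement
#'   between iterations
#' @param cutoff correspondence rejection distance (mm): closest points
#'   farther than this are dropped from the data term for that iteration
#' @return a validated configuration list
#' @export
nonRigidConfig <- function(stiffness = c(50, 20, 5, 2, 0.8), maxIter = 10L,
                           tol = 1e-4, cutoff = 50) {
  stopifnot(length(stiffness) >= 1L, all(stiffness > 0),
            all(diff(stiffness) < 0), maxIter >= 1L, tol > 0, cutoff > 0)
  list(stiffness = as.numeric(stiffness), maxIter = as.integer(maxIter),
       tol = as.numeric(tol), cutoff = as.numeric(cutoff))
}

#' Fit a fixed-topology template to a target surface
#'
#' Deforms the template by one affine transform per vertex, minimizing the
#' distance of each transformed vertex to its closest point on the target
#' surface plus a stiffness penalty on the difference between neighbouring
#' vertices' transforms. The stiffness weight is annealed over
#' `config$stiffness`; each step iterates closest-point search and a sparse
#' linear solve until vertex movement drops below `config$tol`. The output
#' keeps the template's face array and topology tag, which is what gives
#' every registered scan vertex-level correspondence.
#'
#' Meshes are assumed to be rigidly pre-aligned (see [rigidAlign()]).
#'
#' @param template a [TriangleMesh-class] carrying a `topologyId`
#' @param target a [TriangleMesh-class]
#' @param config see [nonRigidConfig()]
#' @return a [RegisteredMesh-class]
#' @export
nonRigidICP <- function(template, target, config = nonRigidConfig()) {
  stopifnot(is(template, "TriangleMesh"), is(target, "TriangleMesh"))
  if (is.na(template@topologyId))
    stop("template must carry a topologyId")
  v0 <- template@vertices
  n <- nrow(v0)

  # node-arc incidence over unique undirected edges
  et <- unique(.edge_table(template@faces))
  ne <- nrow(et)
  M <- Matrix::sparseMatrix(i = rep(seq_len(ne), 2L),
                            j = c(et[, 1L], et[, 2L]),
                            x = rep(c(1, -1), each = ne), dims = c(ne, n))
  G <- Matrix::Diagonal(4L, c(1, 1, 1, 1))
  stiffBlock <- Matrix::kronecker(Matrix::crossprod(M), Matrix::crossprod(G))
  # data matrix D: row i carries [v_i, 1] in columns 4(i-1)+1..4i
  Dj <- as.integer(t(matrix(rep((seq_len(n) - 1L) * 4L, 4L), n, 4L) +
                       rep(1:4, each = n)))
  D <- Matrix::sparseMatrix(i = rep(seq_len(n), each = 4L), j = Dj,
                            x = as.numeric(t(cbind(v0, 1))), dims = c(n, 4L * n))

  # unknowns: X (4n x 3), initialized to the identity transform per vertex
  X <- matrix(0, 4L * n, 3L)
  X[seq(1L, 4L * n, by = 4L), 1L] <- 1
  X[seq(2L, 4L * n, by = 4L), 2L] <- 1
  X[seq(3L, 4L * n, by = 4L), 3L] <- 1

  tv <- target@vertices; tf <- target@faces
  residualHistory <- numeric(0)
  converged <- TRUE
  V <- v0
  for (alpha in config$stiffness) {
    stepConverged <- FALSE
    for (it in seq_len(config$maxIter)) {
      cp <- .closest_point_on_mesh(V, tv, tf)
      w <- cp$distance <= config$cutoff
      if (!any(w)) stop("empty correspondence set: no closest point within cutoff")
      W <- Matrix::Diagonal(n, as.numeric(w))
      WD <- W %*% D
      AtA <- alpha^2 * stiffBlock + Matrix::crossprod(WD)
      AtB <- Matrix::crossprod(WD, W %*% cp$points)
      Xnew <- as.matrix(Matrix::solve(AtA, AtB))
      Vnew <- as.matrix(D %*% Xnew)
      move <- max(sqrt(rowSums((Vnew - V)^2)))
      X <- Xnew; V <- Vnew
      if (move < config$tol) { stepConverged <- TRUE; break }
    }
    if (!stepConverged) converged <- FALSE
    res <- .closest_point_on_mesh(V, tv, tf)$distance
    residualHistory <- c(residualHistory, sqrt(mean(res^2)))
  }
  if (!converged)
    warning("non-rigid ICP hit the iteration cap in at least one stiffness step; ",
            "returning the best result")
  out <- new("TriangleMesh", vertices = V, faces = template@faces,
             topologyId = template@topologyId)
  new("RegisteredMesh", mesh = out,
      residualRMS = residualHistory[length(residualHistory)],
      residualHistory = residualHistory, converged = converged)
}
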