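# fixtures built in code; all randomness under explicit seeds

tetrahedron <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  triangleMesh(v, f)
}

# flat square patch in z = 0, counter-clockwise winding seen from +z
squarePatch <- function(k = 3L) {
  xs <- seq(0, 1, length.out = k + 1L)
  g <- expand.grid(x = xs, y = xs)
  idx <- function(i, j) (j - 1L) * (k + 1L) + i
  f <- NULL
  for (j in seq_len(k)) for (i in seq_len(k)) {
    f <- rbind(f,
               c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
               c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  }
  triangleMesh(cbind(g$x, g$y, 0), f)
}

randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

randomUnitVectors <- function(n) {
  m <- matrix(rnorm(n * 3L), n)
  m / sqrt(rowSums(m^2))
}

# small labelled NDSSet with well-separated synthetic class means
separableNDSSet <- function(width = 60L, nPerClass = 30L, seed = 5L,
                            sdWithin = 0.01) {
  set.seed(seed)
  mus <- list(runif(width), runif(width) + 0.5, 2 * runif(width))
  classes <- c("normocephalic", "trigonocephalic", "scaphocephalic")
  ndsl <- list(); lab <- character(0)
  for (ci in 1:3) for (i in seq_len(nPerClass)) {
    d <- abs(mus[[ci]] + rnorm(width, sd = sdWithin))
    ndsl[[length(ndsl) + 1L]] <- new("NDSVector", densities = d,
                                     nSourceNormals = 100L, bandwidth = 0.2,
                                     kernel = "gaussian", gridHash = "toy")
    lab <- c(lab, classes[ci])
  }
  ndsSet(ndsl, lab)
}

# linear single-layer model for closed-form attribution checks
linearModel <- function(width = 40L, seed = 2L, gridHash = "toy") {
  set.seed(seed)
  W <- matrix(rnorm(width * 3L), width, 3L)
  new("NDSModel", layerDims = c(as.integer(width), 3L), weights = list(W),
      biases = list(numeric(3L)), classLabels = c("a", "b", "c"),
      gridHash = gridHash, trainingFP = list(), scaling = list(),
      seed = 1L, history = list())
}
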