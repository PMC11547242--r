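test_that("attribution is exactly zero when input equals baseline", {
  m <- linearModel(width = 25L)
  ig <- integratedGradients(m, numeric(25L),
                            igConfig(steps = 16L, targetClass = "b"))
  expect_identical(attentionValues(ig), numeric(25L))
  expect_equal(ig@completenessGap, 0, tolerance = 1e-12)
})

test_that("a linear model with zero baseline gives IG = w * x exactly", {
  m <- linearModel(width = 40L)
  set.seed(7)
  x <- runif(40L)
  for (cls in c("a", "b", "c")) {
    ig <- integratedGradients(m, x, igConfig(steps = 8L, targetClass = cls))
    ci <- match(cls, c("a", "b", "c"))
    expect_equal(attentionValues(ig), m@weights[[1L]][, ci] * x,
                 tolerance = 1e-12)
    expect_lt(ig@completenessGap, 1e-10)
  }
})

test_that("completeness gap shrinks below 1% at 512 steps on a trained model", {
  s <- separableNDSSet(width = 40L, nPerClass = 15L)
  parts <- splitDataset(s, seed = 1L)
  m <- trainNDSModel(parts$train, parts$validation, hidden = c(12L, 6L),
                     config = trainConfig(maxEpochs = 30L), seed = 2L)
  x <- SummarizedExperiment::assay(parts$test, "nds")[, 1L]
  cls <- predictNDS(m, as.numeric(x))@scoredClass
  ig <- integratedGradients(m, as.numeric(x),
                            igConfig(steps = 512L, targetClass = cls))
  X <- matrix(as.numeric(x), 1L)
  Fx <- ndshape:::.mlp_logits(m@weights, m@biases, X)[1L,
                                                      match(cls, m@classLabels)]
  F0 <- ndshape:::.mlp_logits(m@weights, m@biases, 0 * X)[1L,
                                                          match(cls, m@classLabels)]
  expect_lt(ig@completenessGap / abs(Fx - F0), 0.01)
})

test_that("projection transports a point-mass attribution to the right vertices", {
  g <- sphereGrid(50L)
  m <- icosphere(2L)
  nrm <- vertexNormals(m)
  vals <- numeric(50L); vals[17L] <- 1
  attr <- new("AttributionVector", values = vals, targetClass = "a",
              completenessGap = 0, gridHash = gridHash(g))
  map <- projectToVertices(attr, g, nrm)
  nearest <- apply(nrm %*% t(gridPoints(g)), 1L, which.max)
  expect_identical(which(attentionValues(map) != 0), which(nearest == 17L))
})

test_that("nearest-grid assignment matches a brute-force angular search", {
  set.seed(3)
  g <- sphereGrid(80L)
  nrm <- randomUnitVectors(200L)
  vals <- rnorm(80L)
  attr <- new("AttributionVector", values = vals, targetClass = "a",
              completenessGap = 0, gridHash = gridHash(g))
  mesh <- icosphere(1L)   # placeholder; projection only uses the normals
  map <- projectToVertices(attr, g, nrm)
  S <- gridPoints(g)
  brute <- vapply(seq_len(200L), function(i) {
    ang <- acos(pmin(pmax(S %*% nrm[i, ], -1), 1))
    vals[which.min(ang)]
  }, numeric(1))
  expect_equal(attentionValues(map), brute, tolerance = 0)
})

test_that("every vertex receives exactly one deterministic value", {
  g <- sphereGrid(30L)
  nrm <- vertexNormals(icosphere(2L))
  attr <- new("AttributionVector", values = rnorm(30L), targetClass = "a",
              completenessGap = 0, gridHash = gridHash(g))
  m1 <- projectToVertices(attr, g, nrm)
  m2 <- projectToVertices(attr, g, nrm)
  expect_identical(attentionValues(m1), attentionValues(m2))
  expect_identical(length(attentionValues(m1)), nrow(nrm))
})

test_that("constant attribution min-max normalizes to zeros with a warning", {
  g <- sphereGrid(20L)
  nrm <- randomUnitVectors(15L)
  attr <- new("AttributionVector", values = rep(0.4, 20L), targetClass = "a",
              completenessGap = 0, gridHash = gridHash(g))
  raw <- projectToVertices(attr, g, nrm)
  expect_true(all(attentionValues(raw) == 0.4))
  expect_warning(mm <- projectToVertices(attr, g, nrm, "minmax"), "constant")
  expect_identical(attentionValues(mm), numeric(15L))
})

test_that("class averaging is identity, cancellation and plain arithmetic", {
  mk <- function(v) new("VertexAttentionMap", values = v, normalization = "raw")
  a <- mk(c(1, 2, 3))
  expect_identical(attentionValues(classAverageMap(list(a))),
                   attentionValues(a))
  expect_identical(attentionValues(classAverageMap(list(a, mk(-c(1, 2, 3))))),
                   c(0, 0, 0))
  cs <- lapply(c(1, 4, 7), function(v) mk(rep(v, 5L)))
  expect_identical(attentionValues(classAverageMap(cs)), rep(4, 5L))
  expect_error(classAverageMap(list(a, mk(c(1, 2)))), "mixed topologies")
})
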