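test_that("sphere grid points are unit, counted, and nearly balanced", {
  g <- sphereGrid(4515L)
  p <- gridPoints(g)
  expect_identical(nrow(p), 4515L)
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 1)), 1e-12)
  expect_lt(sqrt(sum(colMeans(p)^2)), 1e-3)
  expect_error(sphereGrid(11L), "at least 12")
  # deterministic fingerprint, distinct across counts
  expect_identical(gridHash(g), gridHash(sphereGrid(4515L)))
  expect_false(identical(gridHash(g), gridHash(sphereGrid(500L))))
})

test_that("Scott's rule matches its closed form and is monotone in n", {
  # sigma = 0.5, n = 1000, d = 3  ->  0.5 * 1000^(-1/7)
  set.seed(3)
  base <- matrix(rnorm(3000), 1000L)
  nrm <- base / mean(apply(base, 2L, sd)) * 0.5     # force sigma-hat = 0.5
  h <- scottBandwidth(nrm, d = 3L)
  expect_equal(h, 0.5 * 1000^(-1 / 7), tolerance = 1e-12)
  expect_equal(h, 0.18638, tolerance = 1e-5)   # direct evaluation
  # doubling n strictly decreases h at fixed spread
  nrm2 <- rbind(nrm, nrm)
  expect_lt(scottBandwidth(nrm2, 3L), h)
  # stated closed form at sigma 0.3, n 128
  m <- matrix(rnorm(128 * 3), 128L)
  m <- m / mean(apply(m, 2L, sd)) * 0.3
  expect_equal(scottBandwidth(m, 3L), 0.3 * 128^(-1 / 7), tolerance = 1e-12)
  # degenerate spread refuses
  expect_error(scottBandwidth(matrix(rep(c(0, 0, 1), each = 50), 50L)),
               "identical")
})

test_that("a single normal evaluated at itself gives the kernel peak", {
  N <- matrix(c(0, 0, 1), 1L)
  # grid containing the normal itself plus padding
  pts <- rbind(N, randomUnitVectors(19L))
  pts <- pts / sqrt(rowSums(pts^2))
  g <- new("SphereGrid", points = pts, hash = "peak-test")
  f <- densities(evaluateKDE(N, g, kernelConfig("gaussian", bandwidth = 1)))
  expect_equal(f[1L], 1 / sqrt(2 * pi), tolerance = 1e-12)
})

test_that("vectorized KDE equals the double-loop estimator within 1e-12", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:500, 1L)
    k <- sample(12:200, 1L)
    N <- randomUnitVectors(n)
    g <- sphereGrid(k)
    h <- runif(1, 0.05, 0.8)
    f <- densities(evaluateKDE(N, g, kernelConfig("gaussian", bandwidth = h)))
    S <- gridPoints(g)
    brute <- vapply(seq_len(k), function(j) {
      acc <- 0
      for (i in seq_len(n)) {
        u <- sqrt(sum((S[j, ] - N[i, ])^2)) / h
        acc <- acc + exp(-u^2 / 2) / sqrt(2 * pi)
      }
      acc / (n * h)
    }, numeric(1))
    expect_lt(max(abs(f - brute)), 1e-12)
    expect_true(all(f >= 0) && all(is.finite(f)))
  }
})

test_that("the vMF kernel integrates to one over the sphere", {
  set.seed(9)
  N <- randomUnitVectors(40L)
  quad <- sphereGrid(20000L)       # equal-area quadrature
  for (kappa in c(0.5, 2, 50)) {
    f <- densities(evaluateKDE(N, quad,
                               kernelConfig("vmf", bandwidth = 1,
                                            vmfKappa = kappa)))
    expect_equal(mean(f) * 4 * pi, 1, tolerance = 1e-3)
  }
})

test_that("NDS is invariant to translation and uniform scale of the mesh", {
  m <- icosphere(2L)
  g <- sphereGrid(200L)
  base <- extractNDS(m, g, requireTopology = FALSE)
  mt <- triangleMesh(sweep(meshVertices(m), 2L, c(10, -3, 7), "+"),
                     meshFaces(m), check = FALSE)
  expect_equal(densities(extractNDS(mt, g, requireTopology = FALSE)),
               densities(base), tolerance = 1e-12)
  ms <- triangleMesh(meshVertices(m) * 2, meshFaces(m), check = FALSE)
  expect_equal(densities(extractNDS(ms, g, requireTopology = FALSE)),
               densities(base), tolerance = 1e-9)
})

test_that("NDS is rotation-equivariant against the inversely rotated grid", {
  set.seed(6)
  m <- icosphere(2L)
  g <- sphereGrid(150L)
  R <- randomRotation()
  mr <- triangleMesh(meshVertices(m) %*% t(R), meshFaces(m), check = FALSE)
  ndsRot <- extractNDS(mr, g, requireTopology = FALSE)
  gInv <- new("SphereGrid", points = gridPoints(g) %*% R, hash = "rot")
  ndsInv <- extractNDS(m, gInv, requireTopology = FALSE)
  expect_equal(densities(ndsRot), densities(ndsInv), tolerance = 1e-9)
})

test_that("flatter surfaces concentrate normal density", {
  sph <- icosphere(3L)
  v <- meshVertices(sph)
  ell <- triangleMesh(cbind(v[, 1L] * 1.6, v[, 2L], v[, 3L]),
                      meshFaces(sph), check = FALSE)
  g <- sphereGrid(500L)
  h <- 0.25
  fS <- densities(extractNDS(sph, g, kernelConfig(bandwidth = h),
                             requireTopology = FALSE))
  fE <- densities(extractNDS(ell, g, kernelConfig(bandwidth = h),
                             requireTopology = FALSE))
  expect_gt(max(fE), max(fS))
})

test_that("NDSSet round-trips through CSV + sidecar and refuses mixed grids", {
  set.seed(2)
  g1 <- sphereGrid(60L)
  g2 <- sphereGrid(61L)
  n1 <- evaluateKDE(randomUnitVectors(50L), g1, kernelConfig(bandwidth = 0.3))
  n2 <- evaluateKDE(randomUnitVectors(50L), g2, kernelConfig(bandwidth = 0.3))
  expect_error(ndsSet(list(n1, n2), c("a", "b")), "different grids")
  s <- ndsSet(list(n1, n1), c("normocephalic", "scaphocephalic"),
              severity = c(0, 1))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "set.csv")
  writeNDSSet(s, p)
  s2 <- readNDSSet(p)
  expect_equal(SummarizedExperiment::assay(s2, "nds"),
               SummarizedExperiment::assay(s, "nds"), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(gridHash(s2), gridHash(s))
  expect_equal(SummarizedExperiment::colData(s2)$severity, c(0, 1))
})

test_that("unregistered meshes are rejected unless waived", {
  m <- icosphere(1L)
  expect_error(extractNDS(m, sphereGrid(50L)), "topology")
})
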