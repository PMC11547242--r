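test_that("rigid alignment handles identity, translation and random similarity", {
  lm <- landmarkSet(c(90, 0, 0), c(0, 70, 0), c(0, -70, 0))
  tf <- rigidAlign(lm, lm)
  expect_equal(tf@rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf@translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(tf@scale, 1, tolerance = 1e-12)

  shifted <- landmarkSet(c(95, 0, 0), c(5, 70, 0), c(5, -70, 0))
  tf2 <- rigidAlign(shifted, lm)
  expect_equal(tf2@rotation, diag(3), tolerance = 1e-10)
  expect_equal(tf2@translation, c(-5, 0, 0), tolerance = 1e-10)

  set.seed(8)
  for (rep in 1:5) {
    R <- randomRotation()
    s <- runif(1, 0.5, 2)
    t <- rnorm(3, sd = 20)
    moving <- applyTransform(lm, new("RigidTransform", rotation = R,
                                     translation = t, scale = s))
    est <- rigidAlign(moving, lm)
    # est must invert the applied similarity: est.R %*% R == I
    expect_lt(max(abs(est@rotation %*% R - diag(3))), 1e-8)
    expect_equal(est@scale, 1 / s, tolerance = 1e-9)
    back <- applyTransform(moving, est)
    expect_equal(back@nasion, lm@nasion, tolerance = 1e-8)
  }
})

test_that("rigid-only alignment keeps scale fixed at 1", {
  lm <- landmarkSet(c(90, 0, 0), c(0, 70, 0), c(0, -70, 0))
  bigger <- applyTransform(lm, new("RigidTransform", rotation = diag(3),
                                   translation = c(0, 0, 0), scale = 2))
  est <- rigidAlign(bigger, lm, allowScale = FALSE)
  expect_identical(est@scale, 1)
})

test_that("non-rigid ICP is a fixed point on an identical target", {
  tmpl <- makeTemplate(3L)
  reg <- nonRigidICP(tmpl$mesh, tmpl$mesh)
  expect_lt(reg@residualRMS, 1e-6)
  expect_lt(max(abs(meshVertices(reg@mesh) - meshVertices(tmpl$mesh))), 1e-6)
  expect_identical(meshFaces(reg@mesh), meshFaces(tmpl$mesh))
  expect_identical(topologyId(reg@mesh), topologyId(tmpl$mesh))
})

test_that("non-rigid ICP recovers a withheld uniform scale", {
  tmpl <- makeTemplate(3L)
  target <- triangleMesh(meshVertices(tmpl$mesh) * 1.10,
                         meshFaces(tmpl$mesh), check = FALSE)
  reg <- suppressWarnings(nonRigidICP(tmpl$mesh, target))
  bbox <- sqrt(sum((apply(meshVertices(target), 2L, max) -
                      apply(meshVertices(target), 2L, min))^2))
  expect_lt(reg@residualRMS, 0.005 * bbox)
  # residuals are non-increasing across the annealing schedule
  expect_true(all(diff(reg@residualHistory) <= 1e-9))
})

test_that("non-rigid ICP recovers a smooth 5 mm bump to sub-0.5 mm", {
  tmpl <- makeTemplate(3L)
  v <- meshVertices(tmpl$mesh)
  ax <- tmpl$semiAxes
  u <- cbind(v[, 1] / ax[["a"]]^2, v[, 2] / ax[["b"]]^2, v[, 3] / ax[["c"]]^2)
  u <- u / sqrt(rowSums(u^2))
  d2 <- rowSums(sweep(v, 2L, c(0, 0, ax[["c"]]))^2)
  target <- triangleMesh(v + (5 * exp(-d2 / (2 * 20^2))) * u,
                         meshFaces(tmpl$mesh), check = FALSE)
  reg <- suppressWarnings(nonRigidICP(tmpl$mesh, target))
  cp <- ndshape:::.closest_point_on_mesh(meshVertices(reg@mesh),
                                         meshVertices(target),
                                         meshFaces(target))
  expect_lt(mean(cp$distance), 0.5)
  expect_identical(meshFaces(reg@mesh), meshFaces(tmpl$mesh))
})

test_that("registration of the same target twice is bit-reproducible", {
  tmpl <- makeTemplate(3L)
  target <- triangleMesh(meshVertices(tmpl$mesh) * 1.05,
                         meshFaces(tmpl$mesh), check = FALSE)
  r1 <- suppressWarnings(nonRigidICP(tmpl$mesh, target))
  r2 <- suppressWarnings(nonRigidICP(tmpl$mesh, target))
  expect_identical(meshVertices(r1@mesh), meshVertices(r2@mesh))
  expect_identical(r1@residualHistory, r2@residualHistory)
})

test_that("templates without a topology tag and bad configs are rejected", {
  tmpl <- makeTemplate(3L)
  raw <- triangleMesh(meshVertices(tmpl$mesh), meshFaces(tmpl$mesh),
                      check = FALSE)
  expect_error(nonRigidICP(raw, tmpl$mesh), "topologyId")
  expect_error(nonRigidConfig(stiffness = c(1, 5)))    # not decreasing
  expect_error(nonRigidConfig(tol = -1))
})
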