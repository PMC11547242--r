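test_that("the template is deterministic, manifold, with its rim on the plane", {
  t1 <- makeTemplate(3L)
  t2 <- makeTemplate(3L)
  expect_identical(meshVertices(t1$mesh), meshVertices(t2$mesh))
  expect_identical(meshFaces(t1$mesh), meshFaces(t2$mesh))
  expect_true(isManifold(t1$mesh))
  expect_identical(boundaryLoops(t1$mesh), 1L)
  # base-rim vertices lie exactly on the landmark plane (z = 0)
  v <- meshVertices(t1$mesh)
  rim <- which(abs(v[, 3L]) < 1e-9)
  expect_gt(length(rim), 10L)
  expect_lt(max(abs(v[rim, 3L])), 1e-9)
  # landmarks on the rim
  lmm <- rbind(t1$landmarks@nasion, t1$landmarks@tragusLeft,
               t1$landmarks@tragusRight)
  expect_equal(lmm[, 3L], c(0, 0, 0), tolerance = 1e-12)
  expect_error(makeTemplate(7L), "between 3 and 6")
})

test_that("zero severity and zero noise reproduce the template exactly", {
  tmpl <- makeTemplate(3L)
  for (cl in c("normocephalic", "trigonocephalic", "scaphocephalic")) {
    h <- generateHead(headSpec(cl, 0, 0, 1L), tmpl)
    expect_identical(meshVertices(h$mesh), meshVertices(tmpl$mesh))
  }
})

test_that("cephalic index strictly decreases with scaphocephaly severity", {
  tmpl <- makeTemplate(3L)
  ci <- vapply(c(0.2, 0.5, 0.9), function(s)
    generateHead(headSpec("scaphocephalic", s, 0, 1L), tmpl)$groundTruth$cephalicIndex,
    numeric(1))
  expect_true(all(diff(ci) < 0))
})

test_that("wedge angle strictly decreases with trigonocephaly severity", {
  tmpl <- makeTemplate(3L)
  wa <- vapply(c(0.2, 0.5, 0.9), function(s)
    generateHead(headSpec("trigonocephalic", s, 0, 1L), tmpl)$groundTruth$wedgeAngle,
    numeric(1))
  expect_true(all(diff(wa) < 0))
})

test_that("dials stay rank-faithful under 1 mm of smooth noise", {
  tmpl <- makeTemplate(3L)
  set.seed(14)
  sev <- runif(50)
  ci <- numeric(50); wa <- numeric(50)
  for (i in 1:50) {
    ci[i] <- generateHead(headSpec("scaphocephalic", sev[i], 1, 100L + i),
                          tmpl)$groundTruth$cephalicIndex
    wa[i] <- generateHead(headSpec("trigonocephalic", sev[i], 1, 200L + i),
                          tmpl)$groundTruth$wedgeAngle
  }
  expect_gt(cor(sev, -ci, method = "spearman"), 0.95)
  expect_gt(cor(sev, -wa, method = "spearman"), 0.95)
})

test_that("generated heads are already clipped: the landmark clip is a no-op", {
  tmpl <- makeTemplate(3L)
  h <- generateHead(headSpec("scaphocephalic", 0.8, 0.5, 5L), tmpl)
  clipped <- clipNasionTragus(h$mesh, h$landmarks)
  expect_identical(clipped, h$mesh)
})

test_that("datasets have the stated cardinality, topology and determinism", {
  tmpl <- makeTemplate(3L)
  ds <- generateDataset(4L, c(0.2, 0.9), 0.5, seed = 6L, template = tmpl)
  expect_identical(length(ds$meshes), 12L)
  expect_identical(as.integer(table(ds$manifest$label)),
                   c(4L, 4L, 4L))
  for (m in ds$meshes) {
    expect_identical(meshFaces(m), meshFaces(tmpl$mesh))
    expect_identical(topologyId(m), topologyId(tmpl$mesh))
  }
  ds2 <- generateDataset(4L, c(0.2, 0.9), 0.5, seed = 6L, template = tmpl)
  expect_identical(ds2$manifest, ds$manifest)
  expect_identical(meshVertices(ds2$meshes[[7L]]),
                   meshVertices(ds$meshes[[7L]]))
  expect_error(generateDataset(4L, c(0.5, 0.2)), "interval")
  expect_error(generateDataset(4L, c(-0.1, 0.5)), "interval")
})

test_that("severity grading bins into quartile grades 0-3", {
  sev <- seq(0, 1, length.out = 20)
  g <- gradeSeverity(sev)
  expect_setequal(unique(g), 0:3)
  expect_true(!is.unsorted(g))
  expect_identical(as.integer(table(g)), c(5L, 5L, 5L, 5L))
})

test_that("head specifications validate their ranges", {
  expect_error(headSpec("scaphocephalic", 1.2), "severity")
  expect_error(headSpec("scaphocephalic", 0.5, -1), "noiseSD")
  expect_error(headSpec("roundish", 0.5), "arg")
})
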