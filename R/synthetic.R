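## Synthetic craniosynostosis head meshes with a known severity dial.
##
## The generator caricatures the anatomy of the two sagittal/metopic fusion
## phenotypes on a shared fixed-topology template, so that every pipeline
## stage (correspondence, descriptor, classifier, attribution) can be
## validated end to end with known ground truth: scaphocephaly = sagittal
## elongation + biparietal narrowing + vertex depression + occipital pinching
## + frontal bossing; trigonocephaly = forehead wedging + metopic ridge +
## temporal hollowing; normocephaly = the template plus smooth noise.

.smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

#' Synthetic neurocranium template
#'
#' Deterministic half-ellipsoid "neurocranium" (semi-axes 90 x 70 x 65 mm:
#' anteroposterior, lateral, vertical) meshed as a pole-and-rings lattice and
#' cut at its base plane z = 0, on which the nasion and both tragus landmarks
#' lie. Named anatomical zone masks (vertex-index sets) mark where the
#' class-specific deformations act, for later attention-map validation.
#'
#' @param subdivision integer in [3, 6]; 4 gives 2049 vertices
#' @return list with `mesh` (a [TriangleMesh-class] with a fixed topologyId),
#'   `landmarks` (a [LandmarkSet-class]), `zones` (named list of vertex-index
#'   vectors: parietal_flanks, vertex_midline, occiput, forehead, temples,
#'   forehead_left, forehead_right), and `semiAxes`
#' @export
makeTemplate <- function(subdivision = 4L) {
  subdivision <- as.integer(subdivision)
  if (subdivision < 3L || subdivision > 6L)
    stop("subdivision must be between 3 and 6")
  a <- 90; b <- 70; cc <- 65
  m <- 2L^(subdivision + 2L)   # azimuthal segments
  r <- 2L^(subdivision + 1L)   # rings from pole to base
  psi <- 2 * pi * (seq_len(m) - 1L) / m
  theta <- (seq_len(r) / r) * (pi / 2)
  v <- matrix(0, 1L + r * m, 3L)
  v[1L, ] <- c(0, 0, cc)                       # pole
  for (j in seq_len(r)) {
    rows <- 1L + (j - 1L) * m + seq_len(m)
    st <- sin(theta[j]); ct <- cos(theta[j])
    v[rows, ] <- cbind(a * st * cos(psi), b * st * sin(psi), cc * ct)
  }
  v[abs(v) < 1e-13] <- 0                       # exact base plane and axes
  idx <- function(j, k) 1L + (j - 1L) * m + ((k - 1L) %% m) + 1L
  faces <- matrix(0L, m + (r - 1L) * m * 2L, 3L)
  for (k in seq_len(m))                        # pole fan
    faces[k, ] <- c(1L, idx(1L, k), idx(1L, k + 1L))
  row <- m
  for (j in seq_len(r - 1L)) for (k in seq_len(m)) {
    A <- idx(j, k); B <- idx(j, k + 1L)
    C <- idx(j + 1L, k + 1L); D <- idx(j + 1L, k)
    faces[row + 1L, ] <- c(A, D, C)
    faces[row + 2L, ] <- c(A, C, B)
    row <- row + 2L
  }
  mesh <- triangleMesh(v, faces,
                       topologyId = sprintf("hemihead-s%d", subdivision),
                       check = FALSE)
  # outward winding: face normals must point away from the centroid axis
  fn <- faceNormals(mesh)
  ctr <- c(0, 0, cc * 0.3)
  fc <- (v[faces[, 1L], ] + v[faces[, 2L], ] + v[faces[, 3L], ]) / 3
  if (mean(rowSums(fn * sweep(fc, 2L, ctr))) < 0) {
    faces[, 2:3] <- faces[, 3:2]
    mesh <- triangleMesh(v, faces,
                         topologyId = sprintf("hemihead-s%d", subdivision),
                         check = FALSE)
  }
  q <- sweep(v, 2L, c(a, b, cc), "/")          # normalized coordinates
  zones <- list(
    parietal_flanks = which(abs(q[, 2L]) > 0.55 & q[, 3L] > 0.2 &
                              abs(q[, 1L]) < 0.6),
    vertex_midline = which(q[, 3L] > 0.75 & abs(q[, 2L]) < 0.3),
    occiput = which(q[, 1L] < -0.55 & q[, 3L] > 0.1),
    forehead = which(q[, 1L] > 0.55 & q[, 3L] > 0.15),
    temples = which(q[, 1L] > 0.25 & abs(q[, 2L]) > 0.5 &
                      q[, 3L] >= 0 & q[, 3L] < 0.45),
    forehead_left = which(q[, 1L] > 0.45 & q[, 2L] > 0.15 &
                            q[, 3L] > 0.05 & q[, 3L] < 0.7),
    forehead_right = which(q[, 1L] > 0.45 & q[, 2L] < -0.15 &
                             q[, 3L] > 0.05 & q[, 3L] < 0.7))
  landmarks <- landmarkSet(nasion = c(a, 0, 0),
                           tragusLeft = c(0, b, 0),
                           tragusRight = c(0, -b, 0))
  list(mesh = mesh, landmarks = landmarks, zones = zones,
       semiAxes = c(a = a, b = b, c = cc))
}

#' Head specification for the synthetic generator
#'
#' @param classLabel "normocephalic", "trigonocephalic" or "scaphocephalic"
#' @param severity deformation strength in [0, 1]
#' @param noiseSD standard deviation (mm) of the smooth correlated surface
#'   noise (Gaussian bumps, not per-vertex jitter)
#' @param seed integer RNG seed for the noise field
#' @return a validated specification list
#' @export
headSpec <- function(classLabel = c("normocephalic", "trigonocephalic",
                                    "scaphocephalic"),
                     severity = 0.5, noiseSD = 0.5, seed = 1L) {
  classLabel <- match.arg(classLabel)
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]")
  if (!is.finite(noiseSD) || noiseSD < 0) stop("noiseSD must be >= 0")
  list(classLabel = classLabel, severity = as.numeric(severity),
       noiseSD = as.numeric(noiseSD), seed = as.integer(seed))
}

# localized displacement along the outward ellipsoid normal; faded to zero at
# the base rim so generated heads stay clipped at the landmark plane
.gauss_bump <- function(v, u, fade, center, sigma, amplitude) {
  d2 <- rowSums(sweep(v, 2L, center)^2)
  (amplitude * exp(-d2 / (2 * sigma^2)) * fade) * u
}

#' Generate one synthetic head
#'
#' Deforms the template by class-specific smooth displacement fields scaled
#' by severity, then adds smooth correlated noise. The topology (face array
#' and topologyId) never changes, so generated heads share vertex
#' correspondence with the template and each other.
#'
#' @param spec see [headSpec()]
#' @param template from [makeTemplate()]; built at subdivision 4 if missing
#' @return list with `mesh`, `landmarks` (deformed with the head) and
#'   `groundTruth` (spec, zone masks, cephalicIndex, wedgeAngle)
#' @export
generateHead <- function(spec, template = makeTemplate()) {
  v <- template$mesh@vertices
  ax <- template$semiAxes
  a <- ax[["a"]]; b <- ax[["b"]]; cc <- ax[["c"]]
  q <- sweep(v, 2L, c(a, b, cc), "/")
  # outward ellipsoid normal and base fade
  u <- cbind(q[, 1L] / a, q[, 2L] / b, q[, 3L] / cc)
  u <- u / sqrt(rowSums(u^2))
  fade <- .smoothstep(q[, 3L] / 0.15)
  t <- spec$severity
  lm <- .landmark_matrix(template$landmarks)

  if (spec$classLabel == "scaphocephalic") {
    v <- v + .gauss_bump(v, u, fade, c(0, 0, cc), 28, -9 * t) +          # vertex depression
      .gauss_bump(v, u, fade, c(-0.80 * a, 0.5 * b, 0.35 * cc), 24, -6 * t) +
      .gauss_bump(v, u, fade, c(-0.80 * a, -0.5 * b, 0.35 * cc), 24, -6 * t) + # occipital pinching
      .gauss_bump(v, u, fade, c(0.85 * a, 0, 0.45 * cc), 26, 5 * t)      # frontal bossing
    sx <- 1 + 0.25 * t; sy <- 1 - 0.15 * t      # sagittal elongation, biparietal narrowing
    v[, 1L] <- v[, 1L] * sx; v[, 2L] <- v[, 2L] * sy
    lm[, 1L] <- lm[, 1L] * sx; lm[, 2L] <- lm[, 2L] * sy
  } else if (spec$classLabel == "trigonocephalic") {
    w <- .smoothstep(pmax(0, q[, 1L]) / 0.95)   # anterior weight
    v[, 2L] <- v[, 2L] * (1 - 0.45 * t * w)     # forehead wedging
    ridge <- 3.5 * t * exp(-(v[, 2L] / (0.12 * b))^2 / 2) *
      .smoothstep(pmax(0, q[, 1L]) / 0.8) * fade
    v <- v + ridge * u                          # metopic ridge
    v <- v + .gauss_bump(v, u, fade, c(0.5 * a, 0.85 * b, 0.2 * cc), 22, -7 * t) +
      .gauss_bump(v, u, fade, c(0.5 * a, -0.85 * b, 0.2 * cc), 22, -7 * t) # temporal hollowing
  }                                             # normocephalic: severity ignored

  if (spec$noiseSD > 0) {
    set.seed(spec$seed)
    nb <- 12L
    centers <- v[sample.int(nrow(v), nb), , drop = FALSE]
    sigmas <- runif(nb, 15, 35)
    amps <- rnorm(nb, 0, spec$noiseSD)
    for (k in seq_len(nb))
      v <- v + .gauss_bump(v, u, fade, centers[k, ], sigmas[k], amps[k])
  }

  mesh <- new("TriangleMesh", vertices = v, faces = template$mesh@faces,
              topologyId = template$mesh@topologyId)
  landmarks <- landmarkSet(lm[1L, ], lm[2L, ], lm[3L, ])
  gt <- list(spec = spec, zones = template$zones,
             cephalicIndex = cephalicIndex(mesh),
             wedgeAngle = wedgeAngle(mesh, template$zones))
  list(mesh = mesh, landmarks = landmarks, groundTruth = gt)
}

#' Cephalic index of a head mesh
#'
#' Maximum width (lateral, y) divided by maximum length (anteroposterior, x).
#' Decreases with scaphocephaly severity.
#'
#' @param mesh a [TriangleMesh-class] in the generator's coordinate frame
#' @return positive scalar
#' @export
cephalicIndex <- function(mesh) {
  v <- mesh@vertices
  diff(range(v[, 2L])) / diff(range(v[, 1L]))
}

#' Forehead wedge angle
#'
#' Fits a plane (total least squares) to each of the left and right forehead
#' wall zones and returns the interior angle (degrees) between them, measured
#' between the outward plane normals: 180 degrees minus the normals' angle.
#' Decreases with trigonocephaly severity as the forehead narrows to a wedge.
#'
#' @param mesh a [TriangleMesh-class] sharing the template topology
#' @param zones the template's zone masks (needs forehead_left/right)
#' @return angle in degrees
#' @export
wedgeAngle <- function(mesh, zones) {
  planeNormal <- function(idx, side) {
    pts <- mesh@vertices[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    ev <- eigen(crossprod(sweep(pts, 2L, ctr)), symmetric = TRUE)
    n <- ev$vectors[, 3L]
    outward <- c(1, side, 0)        # anterior-lateral reference direction
    if (sum(n * outward) < 0) n <- -n
    n
  }
  nl <- planeNormal(zones$forehead_left, 1)
  nr <- planeNormal(zones$forehead_right, -1)
  180 - acos(pmin(pmax(sum(nl * nr), -1), 1)) * 180 / pi
}

#' Severity grades by quartile
#'
#' Bins continuous severities into the 4-level ordinal scale (0 normal, 1
#' mild, 2 moderate, 3 severe) by the quartiles of the supplied severities,
#' providing the ordinal variable for rank-correlation checks.
#'
#' @param severity numeric vector in [0, 1]
#' @return integer grades 0-3
#' @export
gradeSeverity <- function(severity) {
  qs <- stats::quantile(severity, c(0.25, 0.5, 0.75), names = FALSE)
  findInterval(severity, qs, left.open = TRUE)
}

#' Generate a labelled synthetic dataset
#'
#' Seeded draws of severities (uniform over `severityRange`) and noise for
#' `nPerClass` heads per class. Optionally writes PLY meshes and a manifest
#' CSV (file, label, severity, cephalicIndex, wedgeAngle, seed) to `outDir`.
#'
#' @param nPerClass heads per class (>= 1)
#' @param severityRange severity interval within [0, 1]
#' @param noiseSD smooth-noise standard deviation (mm)
#' @param seed master RNG seed
#' @param classes class labels to generate
#' @param template from [makeTemplate()]
#' @param outDir optional output directory
#' @return list with `meshes` (named list), `landmarks` (named list),
#'   `manifest` (data.frame) and `zones`
#' @export
generateDataset <- function(nPerClass = 100L, severityRange = c(0, 1),
                            noiseSD = 0.5, seed = 1L,
                            classes = c("normocephalic", "trigonocephalic",
                                        "scaphocephalic"),
                            template = makeTemplate(), outDir = NULL) {
  stopifnot(nPerClass >= 1L)
  if (length(severityRange) != 2L || severityRange[1L] > severityRange[2L] ||
      severityRange[1L] < 0 || severityRange[2L] > 1)
    stop("severityRange must be an interval within [0, 1]")
  set.seed(seed)
  total <- nPerClass * length(classes)
  severities <- runif(total, severityRange[1L], severityRange[2L])
  headSeeds <- sample.int(.Machine$integer.max - 1L, total)
  labels <- rep(classes, each = nPerClass)
  meshes <- vector("list", total)
  lms <- vector("list", total)
  ci <- numeric(total); wa <- numeric(total)
  nm <- sprintf("%s_%03d", labels, sequence(rep(nPerClass, length(classes))))
  for (i in seq_len(total)) {
    hs <- headSpec(labels[i], severities[i], noiseSD, headSeeds[i])
    head <- generateHead(hs, template)
    meshes[[i]] <- head$mesh
    lms[[i]] <- head$landmarks
    ci[i] <- head$groundTruth$cephalicIndex
    wa[i] <- head$groundTruth$wedgeAngle
  }
  names(meshes) <- nm; names(lms) <- nm
  manifest <- data.frame(file = paste0(nm, ".ply"), label = labels,
                         severity = severities, cephalicIndex = ci,
                         wedgeAngle = wa, seed = headSeeds,
                         stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(total))
      writeMesh(meshes[[i]], file.path(outDir, manifest$file[i]))
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(meshes = meshes, landmarks = lms, manifest = manifest,
       zones = template$zones)
}
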