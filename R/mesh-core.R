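#' Construct a TriangleMesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm)
#' @param faces m x 3 matrix of 1-based vertex indices
#' @param topologyId optional template-topology tag (NA for raw scans)
#' @param check validate manifoldness of the surface (each edge on at most
#'   two faces); disable only for meshes known to be valid
#' @return a [TriangleMesh-class]
#' @export
triangleMesh <- function(vertices, faces, topologyId = NA_character_, check = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = NULL)
  storage.mode(faces) <- "integer"
  faces <- matrix(faces, ncol = 3L, dimnames = NULL)
  m <- new("TriangleMesh", vertices = vertices, faces = faces,
           topologyId = as.character(topologyId))
  if (check && !isManifold(m))
    stop("mesh is not manifold: an edge is shared by more than two faces")
  m
}

#' Construct a LandmarkSet
#'
#' @param nasion,tragusLeft,tragusRight 3D points in mm
#' @return a [LandmarkSet-class]
#' @export
landmarkSet <- function(nasion, tragusLeft, tragusRight) {
  new("LandmarkSet", nasion = as.numeric(nasion),
      tragusLeft = as.numeric(tragusLeft),
      tragusRight = as.numeric(tragusRight))
}

#' Read landmarks from CSV or JSON
#'
#' CSV must have columns name,x,y,z with names nasion, tragus_left,
#' tragus_right; JSON must be an object with those three keys, each a
#' 3-element coordinate array. Coordinates are millimetres.
#'
#' @param path file path (.csv or .json)
#' @return a [LandmarkSet-class]
#' @export
readLandmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y", "z")
    if (!all(need %in% names(tab)))
      stop("landmark CSV must have columns name,x,y,z")
    rownames(tab) <- tab$name
    get <- function(nm) {
      if (!nm %in% tab$name) stop("missing landmark: ", nm)
      as.numeric(tab[nm, c("x", "y", "z")])
    }
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    get <- function(nm) {
      if (is.null(obj[[nm]])) stop("missing landmark: ", nm)
      as.numeric(obj[[nm]])
    }
  } else stop("unsupported landmark file extension: .", ext)
  landmarkSet(get("nasion"), get("tragus_left"), get("tragus_right"))
}

.landmark_matrix <- function(lm) {
  rbind(lm@nasion, lm@tragusLeft, lm@tragusRight, deparse.level = 0)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Directed edge table: rows (v1, v2) with v1 < v2, three edges per face.
.edge_table <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

#' Manifold and boundary diagnostics
#'
#' A surface patch is manifold here when every undirected edge belongs to at
#' most two faces. `boundaryLoops()` returns the number of connected boundary
#' loops (edges on exactly one face).
#'
#' @param mesh a [TriangleMesh-class]
#' @return `isManifold()`: logical; `boundaryLoops()`: integer count
#' @export
isManifold <- function(mesh) {
  et <- .edge_table(mesh@faces)
  key <- et[, 1L] + (nrow(mesh@vertices) + 1) * as.numeric(et[, 2L])
  max(tabulate(match(key, unique(key)))) <= 2L
}

#' @rdname isManifold
#' @export
boundaryLoops <- function(mesh) {
  et <- .edge_table(mesh@faces)
  key <- et[, 1L] + (nrow(mesh@vertices) + 1) * as.numeric(et[, 2L])
  cnt <- table(key)
  bkey <- as.numeric(names(cnt)[cnt == 1L])
  if (!length(bkey)) return(0L)
  nv1 <- nrow(mesh@vertices) + 1
  v2 <- floor(bkey / nv1); v1 <- bkey - nv1 * v2
  verts <- unique(c(v1, v2))
  idx <- seq_along(verts); names(idx) <- verts
  # union-find over boundary edges
  parent <- idx
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(v1)) {
    a <- find(idx[as.character(v1[k])]); b <- find(idx[as.character(v2[k])])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(idx, find, integer(1))))
}

#' Per-face normals and areas
#'
#' @param mesh a [TriangleMesh-class]
#' @return `faceNormals()`: m x 3 matrix of unit face normals (zero rows for
#'   zero-area faces); `faceAreas()`: numeric vector of triangle areas;
#'   `surfaceArea()`: their sum.
#' @export
faceNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  n
}

#' @rdname faceNormals
#' @export
faceAreas <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  0.5 * sqrt(rowSums(n^2))
}

#' @rdname faceNormals
#' @export
surfaceArea <- function(mesh) sum(faceAreas(mesh))

#' Per-vertex outward unit normals
#'
#' Each vertex normal is the area-weighted average of its incident faces'
#' outward unit normals, renormalized to unit length. These unit vectors are
#' the data points of the spherical density estimate.
#'
#' @param mesh a [TriangleMesh-class] with consistent outward winding
#' @return n x 3 matrix of unit vectors
#' @export
vertexNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  fn <- faceNormals(mesh)
  fa <- faceAreas(mesh)
  w <- fn * fa  # area-weighted unit face normals
  # accumulate face contributions onto vertices (three corners per face)
  idx <- as.integer(f)                      # corner -> vertex index
  acc <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    s <- rowsum(rep(w[, k], 3L), idx)
    acc[as.integer(rownames(s)), k] <- s[, 1L]
  }
  deg <- tabulate(f, nbins = nrow(v))
  if (any(deg == 0L))
    stop("isolated vertex with no incident face: index ",
         which(deg == 0L)[1L])
  len <- sqrt(rowSums(acc^2))
  if (any(len == 0))
    stop("vertex ", which(len == 0)[1L],
         " has only zero-area incident faces; normal undefined")
  acc / len
}

#' Apply a similarity transform to a mesh or landmark set
#'
#' @param x a [TriangleMesh-class] or [LandmarkSet-class]
#' @param transform a [RigidTransform-class]
#' @return the transformed object
#' @export
applyTransform <- function(x, transform) {
  tf <- function(p) transform@scale * (p %*% t(transform@rotation)) +
    rep(transform@translation, each = nrow(p))
  if (is(x, "TriangleMesh")) {
    new("TriangleMesh", vertices = tf(x@vertices), faces = x@faces,
        topologyId = x@topologyId)
  } else if (is(x, "LandmarkSet")) {
    m <- tf(.landmark_matrix(x))
    landmarkSet(m[1L, ], m[2L, ], m[3L, ])
  } else stop("cannot transform object of class ", class(x))
}

#' Clip a head mesh at the nasion-tragus plane
#'
#' Retains the cranial (superior) part of the surface: the side pointed to by
#' the right-handed normal of the landmark triangle ordered (nasion, tragus
#' left, tragus right). Faces crossing the plane are split at their plane
#' intersections so the cut boundary lies exactly on the plane; the new
#' intersection vertices are appended after the retained original vertices.
#' Original vertices no longer referenced by any retained face are dropped.
#'
#' @param mesh a [TriangleMesh-class]
#' @param landmarks a [LandmarkSet-class]; its three points must be
#'   non-collinear
#' @param flip reverse which side counts as superior
#' @return the clipped [TriangleMesh-class]
#' @export
clipNasionTragus <- function(mesh, landmarks, flip = FALSE) {
  stopifnot(is(mesh, "TriangleMesh"), is(landmarks, "LandmarkSet"))
  validObject(landmarks)
  p0 <- landmarks@nasion
  n <- .cross3(landmarks@tragusLeft - p0, landmarks@tragusRight - p0)
  n <- n / sqrt(sum(n^2))
  if (flip) n <- -n
  v <- mesh@vertices
  d <- as.numeric((v - rep(p0, each = nrow(v))) %*% n)
  scale <- max(abs(d), 1)
  tol <- 1e-9 * scale
  keep <- d >= -tol            # on or above the plane
  if (!any(keep)) stop("entire mesh lies inferior to the nasion-tragus plane")
  if (all(keep)) return(mesh)  # no-op: everything already superior
  f <- mesh@faces
  k <- matrix(keep[f], ncol = 3L)
  nkeep <- rowSums(k)

  newV <- list()               # appended intersection vertices
  newF <- list()
  edgeCache <- new.env(hash = TRUE)
  cut_edge <- function(i, j) { # intersection vertex index on edge (i, j)
    key <- paste(min(i, j), max(i, j))
    hit <- edgeCache[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    newV[[length(newV) + 1L]] <<- p
    idx <- nrow(v) + length(newV)
    edgeCache[[key]] <- idx
    idx
  }

  fullFaces <- f[nkeep == 3L, , drop = FALSE]
  mixed <- which(nkeep == 1L | nkeep == 2L)
  for (fi in mixed) {
    tri <- f[fi, ]; kk <- k[fi, ]
    if (sum(kk) == 1L) {
      # one vertex kept: single smaller triangle (rotate so kept is first)
      ord <- c(which(kk), (which(kk) %% 3L) + 1L, ((which(kk) + 1L) %% 3L) + 1L)
      a <- tri[ord[1L]]; b <- tri[ord[2L]]; cc <- tri[ord[3L]]
      pab <- cut_edge(a, b); pca <- cut_edge(cc, a)
      newF[[length(newF) + 1L]] <- c(a, pab, pca)
    } else {
      # two vertices kept: quad split into two triangles
      drop_pos <- which(!kk)
      ord <- c(drop_pos, (drop_pos %% 3L) + 1L, ((drop_pos + 1L) %% 3L) + 1L)
      a <- tri[ord[1L]]; b <- tri[ord[2L]]; cc <- tri[ord[3L]]  # a dropped
      pab <- cut_edge(a, b); pca <- cut_edge(cc, a)
      newF[[length(newF) + 1L]] <- c(pab, b, cc)
      newF[[length(newF) + 1L]] <- c(pab, cc, pca)
    }
  }
  allF <- rbind(fullFaces,
                if (length(newF)) do.call(rbind, newF) else NULL)
  if (!nrow(allF)) stop("clipping removed every face")
  allV <- rbind(v, if (length(newV)) do.call(rbind, newV) else NULL)
  # drop unreferenced vertices, preserving order
  used <- sort(unique(as.integer(allF)))
  remap <- integer(nrow(allV)); remap[used] <- seq_along(used)
  triangleMesh(allV[used, , drop = FALSE],
               matrix(remap[allF], ncol = 3L),
               topologyId = NA_character_, check = FALSE)
}

#' Icosphere test solid
#'
#' Unit icosphere by midpoint subdivision of an icosahedron; subdivision k
#' yields 10*4^k + 2 vertices. Used as a geometric reference surface.
#'
#' @param subdivisions integer >= 0
#' @param radius sphere radius
#' @return a [TriangleMesh-class]
#' @export
icosphere <- function(subdivisions = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    cache <- new.env(hash = TRUE)
    vlist <- as.list(as.data.frame(t(v)))
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- p
      idx <- length(vlist)
      cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; cc <- f[t, 3L]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    v <- v / sqrt(rowSums(v^2))
    f <- nf
  }
  triangleMesh(v * radius, f, check = FALSE)
}
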