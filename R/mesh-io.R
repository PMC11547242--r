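#' Read a triangle mesh from PLY, OBJ or STL
#'
#' PLY is read in both ascii and binary (little/big endian) dialects; STL in
#' ascii and binary. STL stores bare triangle soup, so identical vertex
#' coordinates are welded into shared vertices on load (order of first
#' appearance). Vertex order is otherwise preserved as stored.
#'
#' @param path file path
#' @param format one of "ply", "obj", "stl" or "auto" (from the extension)
#' @return a [TriangleMesh-class]
#' @export
readMesh <- function(path, format = c("auto", "ply", "obj", "stl")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj", "stl"))
      stop("cannot infer mesh format from extension '.", ext,
           "'; pass format= explicitly (ply/obj/stl)")
    format <- ext
  }
  if (!file.exists(path)) stop("no such file: ", path)
  mesh <- switch(format,
                 ply = .read_ply(path),
                 obj = .read_obj(path),
                 stl = .read_stl(path))
  validObject(mesh)
  if (!isManifold(mesh)) stop("mesh in ", path, " is not a manifold surface")
  mesh
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' PLY defaults to binary little-endian with double-precision coordinates
#' (`ascii = TRUE` writes the ascii dialect); STL is written binary. An
#' optional per-vertex scalar is stored as a PLY `quality` property (used for
#' attention maps); it is ignored for OBJ/STL.
#'
#' @param mesh a [TriangleMesh-class]
#' @param path output path
#' @param format "auto" (extension), "ply", "obj" or "stl"
#' @param ascii write the ascii dialect where the format has one
#' @param quality optional numeric per-vertex scalar channel (PLY only)
#' @return `path`, invisibly
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "obj", "stl"),
                      ascii = FALSE, quality = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "obj", "stl"))
      stop("cannot infer mesh format from extension '.", ext, "'")
    format <- ext
  }
  if (!is.null(quality) && length(quality) != nrow(mesh@vertices))
    stop("quality channel length must equal the vertex count")
  switch(format,
         ply = .write_ply(mesh, path, ascii = ascii, quality = quality),
         obj = .write_obj(mesh, path),
         stl = .write_stl(mesh, path, ascii = ascii))
  invisible(path)
}

## ---- PLY ----

.ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw, off, type, endian) {
  sz <- .ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  val <- readBin(raw[(off + 1L):(off + sz)], what = what, n = 1L, size = sz,
                 endian = endian,
                 signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  list(value = as.numeric(val), off = off + sz)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; endian <- "little"
  elements <- list()  # list of list(name, count, props = list(name, type, listCount, listType))
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (!length(tok) || tok[1L] == "comment") next
    if (tok[1L] == "format") {
      fmt <- tok[2L]
      if (fmt == "binary_big_endian") endian <- "big"
    } else if (tok[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property") {
      if (tok[2L] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5L], type = NA, listCount = tok[3L], listType = tok[4L])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3L], type = tok[2L], listCount = NA, listType = NA)
      }
    } else if (tok[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex or face elements")

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    ptr <- 0L
    nextrow <- function() { ptr <<- ptr + 1L; strsplit(trimws(txt[ptr]), "\\s+")[[1L]] }
    parse_el <- function(el) {
      out <- vector("list", el$count)
      for (i in seq_len(el$count)) out[[i]] <- as.numeric(nextrow())
      out
    }
    rows <- list()
    for (el in elements) rows[[el$name]] <- parse_el(el)
    vp <- vapply(elements$vertex$props, function(p) p$name, character(1))
    vmat <- do.call(rbind, rows$vertex)
    verts <- vmat[, match(c("x", "y", "z"), vp), drop = FALSE]
    faces <- do.call(rbind, lapply(rows$face, function(r) {
      if (r[1L] != 3) stop("only triangular PLY faces are supported")
      r[2:4] + 1
    }))
  } else {
    raw <- readBin(con, what = "raw", n = file.info(path)$size)
    off <- 0L
    verts <- NULL; faces <- NULL
    for (el in elements) {
      listProps <- any(!vapply(el$props, function(p) is.na(p$listCount), logical(1)))
      if (!listProps) {
        sizes <- vapply(el$props, function(p) .ply_type_size[[p$type]], integer(1))
        rec <- sum(sizes)
        types <- vapply(el$props, function(p) p$type, character(1))
        if (all(types == types[1L])) {
          # homogeneous record: bulk read
          sz <- sizes[1L]
          what <- if (types[1L] %in% c("float", "float32", "double", "float64"))
            "double" else "integer"
          vals <- readBin(raw[(off + 1L):(off + rec * el$count)], what = what,
                          n = length(sizes) * el$count, size = sz, endian = endian,
                          signed = !(types[1L] %in% c("uchar", "uint8", "ushort", "uint16")))
          m <- matrix(as.numeric(vals), ncol = length(sizes), byrow = TRUE)
          off <- off + rec * el$count
        } else {
          m <- matrix(NA_real_, el$count, length(el$props))
          for (i in seq_len(el$count)) for (j in seq_along(el$props)) {
            r <- .ply_read_scalar(raw, off, el$props[[j]]$type, endian)
            m[i, j] <- r$value; off <- r$off
          }
        }
        if (el$name == "vertex") {
          vp <- vapply(el$props, function(p) p$name, character(1))
          verts <- m[, match(c("x", "y", "z"), vp), drop = FALSE]
        }
      } else {
        rowsF <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          for (p in el$props) {
            if (!is.na(p$listCount)) {
              r <- .ply_read_scalar(raw, off, p$listCount, endian)
              cnt <- as.integer(r$value); off <- r$off
              vals <- numeric(cnt)
              for (q in seq_len(cnt)) {
                r <- .ply_read_scalar(raw, off, p$listType, endian)
                vals[q] <- r$value; off <- r$off
              }
              if (el$name == "face" && p$name %in% c("vertex_indices", "vertex_index")) {
                if (cnt != 3L) stop("only triangular PLY faces are supported")
                rowsF[[i]] <- vals + 1
              }
            } else {
              r <- .ply_read_scalar(raw, off, p$type, endian); off <- r$off
            }
          }
        }
        if (el$name == "face") faces <- do.call(rbind, rowsF)
      }
    }
  }
  triangleMesh(verts, faces, check = FALSE)
}

.write_ply <- function(mesh, path, ascii = FALSE, quality = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  hdr <- c("ply",
           if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (!is.null(quality)) "property double quality",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (ascii) {
    vm <- v
    if (!is.null(quality)) vm <- cbind(vm, quality)
    vl <- apply(vm, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
    fl <- apply(f, 1L, function(r) paste(c(3L, r - 1L), collapse = " "))
    writeLines(c(hdr, vl, fl), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    vm <- if (is.null(quality)) v else cbind(v, quality)
    writeBin(as.numeric(t(vm)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

## ---- OBJ ----

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (!length(vlines) || !length(flines)) stop("OBJ file lacks v/f records")
  verts <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(t)
    as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(t) {
    idx <- vapply(t[-1L], function(s) as.integer(strsplit(s, "/")[[1L]][1L]),
                  integer(1))
    if (length(idx) != 3L) stop("only triangular OBJ faces are supported")
    idx
  }))
  triangleMesh(verts, faces, check = FALSE)
}

.write_obj <- function(mesh, path) {
  vl <- apply(mesh@vertices, 1L, function(r)
    sprintf("v %.17g %.17g %.17g", r[1L], r[2L], r[3L]))
  fl <- apply(mesh@faces, 1L, function(r) sprintf("f %d %d %d", r[1L], r[2L], r[3L]))
  writeLines(c(vl, fl), path)
  invisible(path)
}

## ---- STL ----

.read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = min(80L, sz))
  if (identical(rawToChar(head80[1:5]), "solid")) {
    # probably ascii; binary headers rarely start with 'solid'
    txt <- suppressWarnings(readLines(path, warn = FALSE))
    if (any(grepl("facet normal", txt, fixed = TRUE))) {
      vloc <- grep("^\\s*vertex", txt)
      coords <- do.call(rbind, lapply(strsplit(trimws(txt[vloc]), "\\s+"),
                                      function(t) as.numeric(t[2:4])))
      return(.weld_soup(coords))
    }
  }
  seek(con, 80L)
  ntri <- readBin(con, "integer", size = 4L, endian = "little")
  raw <- readBin(con, "raw", n = 50L * ntri)
  idx <- rep(seq_len(ntri) - 1L, each = 48L) * 50L +
    rep(seq_len(48L), times = ntri)
  floats <- readBin(raw[idx], "double", size = 4L, n = 12L * ntri,
                    endian = "little")
  m <- matrix(floats, ncol = 12L, byrow = TRUE)   # normal + 3 vertices
  coords <- matrix(t(m[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  .weld_soup(coords)
}

.weld_soup <- function(coords) {
  if (nrow(coords) %% 3L != 0L) stop("corrupt STL triangle soup")
  key <- apply(coords, 1L, function(r) paste(sprintf("%.9g", r), collapse = ","))
  first <- !duplicated(key)
  verts <- coords[first, , drop = FALSE]
  idx <- match(key, key[first])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangleMesh(verts, faces, check = FALSE)
}

.write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh@vertices; f <- mesh@faces
  fn <- faceNormals(mesh)
  if (ascii) {
    out <- c("solid ndshape")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      out <- c(out,
               sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
               "    endloop", "  endfacet")
    }
    writeLines(c(out, "endsolid ndshape"), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      tri <- v[f[i, ], , drop = FALSE]
      writeBin(as.numeric(c(fn[i, ], t(tri))), con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
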