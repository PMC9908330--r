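#' Read a triangulated surface mesh
#'
#' Supports PLY (ascii and binary little-endian), STL (ascii and binary)
#' and OBJ (v/f records; textures and normals ignored). Vertex order is
#' preserved for PLY and OBJ; STL stores unindexed facets, so duplicate
#' vertex records are merged by exact coordinate equality (deterministic,
#' first-occurrence order).
#'
#' @param path file to read.
#' @param format one of "auto", "ply", "stl", "obj"; "auto" uses the file
#'   extension.
#' @return a [TriangleMesh-class] named after the file.
#' @export
readMesh <- function(path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "stl", "obj"))
      stop("cannot guess mesh format from extension '", format, "'")
  }
  vf <- switch(format, ply = readPLY(path), stl = readSTL(path),
               obj = readOBJ(path))
  triangleMesh(vf$vertices, vf$faces,
               name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a triangulated surface mesh
#'
#' PLY is written with double-precision coordinates (binary little-endian
#' by default, or full-precision ascii), so a PLY round-trip reproduces
#' the mesh bit-exactly. STL is inherently single-precision and
#' unindexed; OBJ is ascii with full-precision coordinates.
#'
#' @param mesh a valid [TriangleMesh-class]; validated before any file is
#'   created.
#' @param path output file.
#' @param format one of "auto", "ply", "stl", "obj".
#' @param binary write binary PLY/STL (ignored for OBJ).
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "stl", "obj"),
                      binary = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "stl", "obj"))
      stop("cannot guess mesh format from extension '", format, "'")
  }
  rep <- validateMesh(mesh)
  if (nrow(rep) > 0)
    stop("refusing to write invalid mesh: ", rep$message[1])
  switch(format,
         ply = writePLY(mesh, path, binary),
         stl = writeSTL(mesh, path, binary),
         obj = writeOBJ(mesh, path))
  invisible(path)
}

## ---- PLY ----

.plyTypes <- list(
  char = c(1, "integer", TRUE), int8 = c(1, "integer", TRUE),
  uchar = c(1, "integer", FALSE), uint8 = c(1, "integer", FALSE),
  short = c(2, "integer", TRUE), int16 = c(2, "integer", TRUE),
  ushort = c(2, "integer", FALSE), uint16 = c(2, "integer", FALSE),
  int = c(4, "integer", TRUE), int32 = c(4, "integer", TRUE),
  uint = c(4, "integer", TRUE), uint32 = c(4, "integer", TRUE),
  float = c(4, "double", TRUE), float32 = c(4, "double", TRUE),
  double = c(8, "double", TRUE), float64 = c(8, "double", TRUE))

readPLY <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  m <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(m) == 0) stop("not a PLY file (no end_header): ", path)
  nl <- m + 10L
  if (nl <= length(raw) && raw[nl] == as.raw(13L)) nl <- nl + 1L
  if (nl > length(raw) || raw[nl] != as.raw(10L))
    stop("malformed PLY header: ", path)
  header <- rawToChar(raw[seq_len(m - 1L)])
  dataOffset <- nl
  lines <- strsplit(header, "\r?\n")[[1]]
  if (!grepl("^ply", lines[1])) stop("not a PLY file: ", path)
  fmtLine <- grep("^format ", lines, value = TRUE)[1]
  fmt <- strsplit(trimws(fmtLine), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)

  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment") next
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, countType = tok[3],
               valueType = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY lacks vertex or face element: ", path)

  if (fmt == "ascii") {
    tokens <- scan(text = rawToChar(raw[(dataOffset + 1L):length(raw)]),
                   what = character(), quiet = TRUE, comment.char = "")
    pos <- 1L
    V <- NULL; FF <- NULL
    for (el in elements) {
      if (el$name == "vertex") {
        p <- length(el$props)
        vals <- as.numeric(tokens[pos:(pos + el$count * p - 1L)])
        pos <- pos + el$count * p
        mat <- matrix(vals, ncol = p, byrow = TRUE)
        idx <- match(c("x", "y", "z"),
                     vapply(el$props, `[[`, "", "name"))
        if (anyNA(idx)) stop("PLY vertex element lacks x/y/z")
        V <- mat[, idx, drop = FALSE]
      } else if (el$name == "face") {
        FF <- matrix(0L, el$count, 3)
        for (i in seq_len(el$count)) {
          k <- as.integer(tokens[pos]); pos <- pos + 1L
          if (k != 3L) stop("PLY face ", i, " is not a triangle")
          FF[i, ] <- as.integer(tokens[pos:(pos + 2L)]) + 1L
          pos <- pos + 3L
        }
      } else {
        # skip unknown scalar-only elements
        p <- length(el$props)
        if (any(vapply(el$props, `[[`, TRUE, "list")))
          stop("cannot skip PLY list element '", el$name, "'")
        pos <- pos + el$count * p
      }
    }
  } else {
    off <- dataOffset
    V <- NULL; FF <- NULL
    for (el in elements) {
      isList <- vapply(el$props, `[[`, TRUE, "list")
      if (el$name == "face") {
        p1 <- el$props[[which(isList)[1]]]
        ct <- .plyTypes[[p1$countType]]; vt <- .plyTypes[[p1$valueType]]
        cs <- as.integer(ct[1]); vs <- as.integer(vt[1])
        FF <- matrix(0L, el$count, 3)
        for (i in seq_len(el$count)) {
          k <- readBin(raw[(off + 1L):(off + cs)], ct[2], n = 1,
                       size = cs, endian = "little",
                       signed = as.logical(ct[3]))
          off <- off + cs
          if (k != 3L) stop("PLY face ", i, " is not a triangle")
          FF[i, ] <- as.integer(
            readBin(raw[(off + 1L):(off + 3L * vs)], vt[2], n = 3,
                    size = vs, endian = "little")) + 1L
          off <- off + 3L * vs
        }
      } else {
        if (any(isList))
          stop("cannot parse PLY list property in element '", el$name, "'")
        sizes <- vapply(el$props, function(p)
          as.integer(.plyTypes[[p$type]][1]), 0L)
        stride <- sum(sizes)
        block <- raw[(off + 1L):(off + stride * el$count)]
        off <- off + stride * el$count
        if (el$name == "vertex") {
          cols <- list()
          starts <- cumsum(c(0L, sizes))
          for (j in seq_along(el$props)) {
            t <- .plyTypes[[el$props[[j]]$type]]
            sz <- as.integer(t[1])
            sel <- as.vector(outer(seq_len(sz),
                                   starts[j] + stride * (seq_len(el$count) - 1L),
                                   "+"))
            cols[[el$props[[j]]$name]] <-
              readBin(block[sel], t[2], n = el$count, size = sz,
                      endian = "little",
                      signed = if (t[2] == "integer" && sz < 4)
                        as.logical(t[3]) else TRUE)
          }
          if (!all(c("x", "y", "z") %in% names(cols)))
            stop("PLY vertex element lacks x/y/z")
          V <- cbind(cols$x, cols$y, cols$z)
        }
      }
    }
  }
  list(vertices = V, faces = FF)
}

writePLY <- function(mesh, path, binary = TRUE) {
  V <- mesh@vertices
  FF <- mesh@faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0"
           else "format ascii 1.0",
           sprintf("element vertex %d", nrow(V)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(FF)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.vector(t(V)), con, size = 8, endian = "little")
    idx <- writeBin(as.integer(t(FF) - 1L), raw(), size = 4,
                    endian = "little")
    idx <- matrix(idx, nrow = 12)
    rec <- rbind(matrix(rep(as.raw(3), nrow(FF)), nrow = 1), idx)
    writeBin(as.vector(rec), con)
  } else {
    writeLines(sprintf("%.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", FF[, 1] - 1L, FF[, 2] - 1L,
                       FF[, 3] - 1L), con)
  }
}

## ---- STL ----

readSTL <- function(path) {
  size <- file.size(path)
  raw <- readBin(path, "raw", size)
  isBinary <- FALSE
  if (size >= 84) {
    n <- readBin(raw[81:84], "integer", n = 1, size = 4, endian = "little")
    if (!is.na(n) && n >= 0 && size == 84 + 50 * as.double(n))
      isBinary <- TRUE
  }
  if (isBinary) {
    n <- readBin(raw[81:84], "integer", n = 1, size = 4, endian = "little")
    # facet record: 12 float32 (normal + 3 vertices) + uint16 attribute
    sel <- as.vector(outer(seq_len(36),
                           84 + 12 + 50 * (seq_len(n) - 1L), "+"))
    coords <- readBin(raw[sel], "double", n = 9L * n, size = 4,
                      endian = "little")
    rec <- matrix(coords, ncol = 3, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("malformed ascii STL: ", path)
    toks <- strsplit(trimws(vl), "\\s+")
    rec <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  }
  # merge duplicate facet vertices by exact coordinate equality
  key <- sprintf("%.17g_%.17g_%.17g", rec[, 1], rec[, 2], rec[, 3])
  keep <- !duplicated(key)
  V <- rec[keep, , drop = FALSE]
  idx <- match(key, key[keep])
  FF <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = V, faces = FF)
}

writeSTL <- function(mesh, path, binary = TRUE) {
  V <- mesh@vertices
  FF <- mesh@faces
  a <- V[FF[, 1], , drop = FALSE]
  b <- V[FF[, 2], , drop = FALSE]
  cc <- V[FF[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(rep(as.raw(0), 80), con)
    writeBin(as.integer(nrow(FF)), con, size = 4, endian = "little")
    dat <- t(cbind(nrm, a, b, cc))  # 12 floats per facet
    fl <- writeBin(as.vector(dat), raw(), size = 4, endian = "little")
    fl <- matrix(fl, nrow = 48)
    rec <- rbind(fl, matrix(as.raw(0), 2, nrow(FF)))
    writeBin(as.vector(rec), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("solid ", mesh@name), con)
    for (f in seq_len(nrow(FF))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", nrm[f, 1], nrm[f, 2],
                nrm[f, 3]),
        "    outer loop",
        sprintf("      vertex %.17g %.17g %.17g",
                c(a[f, 1], b[f, 1], cc[f, 1]),
                c(a[f, 2], b[f, 2], cc[f, 2]),
                c(a[f, 3], b[f, 3], cc[f, 3])),
        "    endloop", "  endfacet"), con)
    }
    writeLines(paste0("endsolid ", mesh@name), con)
  }
}

## ---- OBJ ----

readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(fl) == 0)
    stop("OBJ lacks v or f records: ", path)
  vt <- strsplit(trimws(vl), "\\s+")
  V <- t(vapply(vt, function(t) as.numeric(t[2:4]), numeric(3)))
  ft <- strsplit(trimws(fl), "\\s+")
  FF <- t(vapply(ft, function(t) {
    if (length(t) != 4) stop("OBJ face is not a triangle")
    idx <- as.integer(vapply(strsplit(t[2:4], "/"), `[[`, "", 1))
    if (any(idx < 1)) stop("negative OBJ indices are not supported")
    idx
  }, integer(3)))
  list(vertices = V, faces = FF)
}

writeOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh@vertices
  FF <- mesh@faces
  writeLines(sprintf("v %.17g %.17g %.17g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", FF[, 1], FF[, 2], FF[, 3]), con)
}
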