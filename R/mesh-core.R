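#' Construct a TriangleMesh
#'
#' @param vertices numeric matrix (or coercible) with 3 columns, one row
#'   per vertex, coordinates in mm.
#' @param faces matrix with 3 columns of 1-based vertex indices.
#' @param name identifier carried through the pipeline.
#' @param validate run the full validity check (disable only for meshes
#'   known valid by construction).
#' @return a [TriangleMesh-class].
#' @examples
#' m <- triangleMesh(
#'   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
#'   name = "tetra")
#' nVertices(m)
#' @export
triangleMesh <- function(vertices, faces, name = "", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- new("TriangleMesh", vertices = vertices, faces = faces,
           name = as.character(name)[1])
  if (validate) {
    rep <- validateMesh(m)
    if (nrow(rep) > 0)
      stop("invalid mesh '", name, "': ", rep$message[1],
           if (nrow(rep) > 1) sprintf(" (and %d more)", nrow(rep) - 1))
  }
  m
}

# shared by the S4 validity method and validateMesh()
validateMeshCore <- function(V, FF) {
  out <- list()
  add <- function(type, index, message)
    out[[length(out) + 1]] <<- data.frame(type = type, index = index,
                                          message = message)
  if (ncol(V) != 3) add("shape", NA_integer_, "vertices must have 3 columns")
  if (ncol(FF) != 3) add("shape", NA_integer_, "faces must have 3 columns")
  if (length(out) == 0) {
    nv <- nrow(V)
    if (nv < 4) add("size", NA_integer_,
                    sprintf("vertex count %d < 4", nv))
    if (nrow(FF) < 4) add("size", NA_integer_,
                          sprintf("face count %d < 4", nrow(FF)))
    bad <- which(!is.finite(V), arr.ind = TRUE)
    for (i in unique(bad[, 1]))
      add("non-finite coordinate", i,
          sprintf("vertex %d has a non-finite coordinate", i))
    if (nrow(FF) > 0) {
      oob <- which(FF < 1L | FF > nv, arr.ind = TRUE)
      for (f in unique(oob[, 1]))
        add("index out of range", f,
            sprintf("face %d references a vertex outside 1..%d", f, nv))
      dg <- which(FF[, 1] == FF[, 2] | FF[, 1] == FF[, 3] |
                    FF[, 2] == FF[, 3])
      for (f in dg)
        add("degenerate face", f,
            sprintf("face %d repeats a vertex index", f))
    }
  }
  if (length(out) == 0)
    data.frame(type = character(), index = integer(), message = character())
  else do.call(rbind, out)
}

#' Validate a mesh and report every violation
#'
#' Checks all TriangleMesh invariants (finite coordinates, in-range
#' non-degenerate faces, minimum size) and returns one row per violation;
#' an empty report means the mesh is valid. Reports rather than throws.
#'
#' @param mesh a [TriangleMesh-class] (possibly invalid, e.g. built with
#'   `validate = FALSE`).
#' @return data.frame with columns `type`, `index` (offending element,
#'   1-based), `message`.
#' @export
validateMesh <- function(mesh) {
  validateMeshCore(mesh@vertices, mesh@faces)
}

#' @rdname TriangleMesh-class
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)

#' @rdname TriangleMesh-class
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)

#' @rdname TriangleMesh-class
#' @export
setMethod("meshName", "TriangleMesh", function(x) x@name)

#' @rdname TriangleMesh-class
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' @rdname TriangleMesh-class
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

setMethod("show", "TriangleMesh", function(object) {
  bb <- apply(object@vertices, 2, range)
  cat(sprintf("TriangleMesh '%s': %d vertices, %d faces\n",
              object@name, nrow(object@vertices), nrow(object@faces)))
  cat(sprintf("  bounding box (mm): [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

#' Construct a RigidTransform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric (mm).
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; the axis is normalised internally.
#'
#' @param axis length-3 direction of the rotation axis.
#' @param angleDeg rotation angle in degrees (right-handed).
#' @return a 3x3 rotation matrix.
#' @export
rotationAxisAngle <- function(axis, angleDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname RigidTransform-class
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @rdname RigidTransform-class
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, x) {
    sweep(x %*% t(transform@rotation), 2, transform@translation, "+")
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("RigidTransform", "TriangleMesh"),
  function(transform, x) {
    x@vertices <- applyTransform(transform, x@vertices)
    x
  })

#' Compose and invert rigid transforms
#'
#' `composeTransforms(a, b)` is the transform applying `b` first, then
#' `a`; `invertTransform(a)` is its inverse.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(a) {
  rigidTransform(t(a@rotation), as.numeric(-t(a@rotation) %*% a@translation))
}

#' Rotation angle of a rigid transform
#'
#' @param a a [RigidTransform-class].
#' @return the rotation angle in degrees, in [0, 180].
#' @export
rotationAngle <- function(a) {
  ct <- (sum(diag(a@rotation)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm\n",
              rotationAngle(object), object@translation[1],
              object@translation[2], object@translation[3]))
})

# flatten V x 3 coordinates vertex-major (x1,y1,z1,x2,...) and back
flattenCoords <- function(V) as.vector(t(V))
unflattenCoords <- function(x) matrix(x, ncol = 3, byrow = TRUE)

# edge list (each undirected edge once) of a face matrix
meshEdges <- function(FF) {
  e <- rbind(FF[, c(1, 2)], FF[, c(2, 3)], FF[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic of a mesh
#'
#' V - E + F with each undirected edge counted once; 2 for a closed
#' genus-0 surface.
#'
#' @param mesh a [TriangleMesh-class].
#' @return integer Euler characteristic.
#' @export
eulerCharacteristic <- function(mesh) {
  nrow(mesh@vertices) - nrow(meshEdges(mesh@faces)) + nrow(mesh@faces)
}
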