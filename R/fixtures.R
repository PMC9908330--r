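#' Analytic test surfaces
#'
#' `icosphereMesh` subdivides an icosahedron and projects vertices onto a
#' sphere; `torusMesh` builds a ring torus. Both are closed, so they carry
#' analytic Gaussian curvature (1/r^2 on the sphere; sign split between
#' outer and inner torus halves) and exact Gauss-Bonnet sums, which makes
#' them the standard fixtures for validating discrete curvature.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (0 gives the
#'   icosahedron).
#' @param radius sphere radius (mm).
#' @return a [TriangleMesh-class].
#' @export
icosphereMesh <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  FF <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env(hash = TRUE)
    Vlist <- asplit(V, 1)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- mget(key, envir = mid, ifnotfound = list(NULL))[[1]]
      if (!is.null(id)) return(id)
      Vlist[[length(Vlist) + 1]] <<- (Vlist[[i]] + Vlist[[j]]) / 2
      assign(key, length(Vlist), envir = mid)
      length(Vlist)
    }
    newF <- matrix(0L, 4 * nrow(FF), 3)
    for (f in seq_len(nrow(FF))) {
      a <- FF[f, 1]; b <- FF[f, 2]; cc <- FF[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(cc, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, Vlist)
    FF <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  triangleMesh(V, FF, name = sprintf("icosphere_r%g", radius))
}

#' @rdname icosphereMesh
#' @param majorRadius distance from torus centre to tube centre (mm).
#' @param tubeRadius tube radius (mm); must be < `majorRadius`.
#' @param nMajor,nTube grid resolution around the two circles.
#' @export
torusMesh <- function(majorRadius = 10, tubeRadius = 3, nMajor = 48,
                      nTube = 24) {
  stopifnot(tubeRadius < majorRadius)
  iu <- rep(seq_len(nMajor) - 1L, each = nTube)
  iv <- rep(seq_len(nTube) - 1L, times = nMajor)
  u <- 2 * pi * iu / nMajor
  v <- 2 * pi * iv / nTube
  V <- cbind((majorRadius + tubeRadius * cos(v)) * cos(u),
             (majorRadius + tubeRadius * cos(v)) * sin(u),
             tubeRadius * sin(v))
  vid <- function(i, j) ((i %% nMajor) * nTube + (j %% nTube)) + 1L
  i <- rep(0:(nMajor - 1L), each = nTube)
  j <- rep(0:(nTube - 1L), times = nMajor)
  FF <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
              cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  triangleMesh(V, FF, name = "torus")
}

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted face sampling with uniform barycentric coordinates.
#' Consumes the current RNG stream; seed beforehand for reproducibility.
#'
#' @param mesh a [TriangleMesh-class].
#' @param n number of points.
#' @return an n x 3 matrix of surface points (mm).
#' @export
sampleSurfacePoints <- function(mesh, n) {
  V <- mesh@vertices
  FF <- mesh@faces
  a <- V[FF[, 1], , drop = FALSE]
  b <- V[FF[, 2], , drop = FALSE]
  cc <- V[FF[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  f <- sample.int(nrow(FF), n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  w1 <- 1 - r1
  w2 <- r1 * (1 - r2)
  w3 <- r1 * r2
  w1 * a[f, , drop = FALSE] + w2 * b[f, , drop = FALSE] +
    w3 * cc[f, , drop = FALSE]
}
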