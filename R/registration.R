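asPoints <- function(x) {
  if (is(x, "TriangleMesh")) return(x@vertices)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

checkNondegenerate <- function(P, what) {
  if (nrow(P) < 3) stop(what, " must contain at least 3 points")
  Pc <- sweep(P, 2, colMeans(P))
  ev <- eigen(crossprod(Pc), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12 * max(ev[1], .Machine$double.xmin))
    stop(what, " points are collinear or coincident")
}

#' Rigid coherent point drift registration
#'
#' Registers `source` onto `target` with the rigid (rotation +
#' translation, no scaling) coherent point drift algorithm: EM over a
#' Gaussian mixture with a single isotropic variance, the rigid update
#' obtained from an SVD of the weighted cross-covariance. Deterministic
#' given its inputs.
#'
#' @param source,target point sets: n x 3 matrices or
#'   [TriangleMesh-class] objects (vertices are used).
#' @param maxIter maximum EM iterations.
#' @param tol relative change of the negative log-likelihood at which to
#'   declare convergence.
#' @param outlierWeight uniform-outlier mixture weight in [0, 1).
#' @return a list: `transform` ([RigidTransform-class] mapping source
#'   onto target), `objective` (final negative log-likelihood), `sigma2`,
#'   `iterations`, and `converged` (FALSE flags stopping at `maxIter`
#'   without meeting `tol`; no exception is thrown).
#' @export
cpdRigid <- function(source, target, maxIter = 100, tol = 1e-6,
                     outlierWeight = 0) {
  Y <- asPoints(source)
  X <- asPoints(target)
  checkNondegenerate(Y, "source")
  checkNondegenerate(X, "target")

  Rm <- diag(3)
  tv <- c(0, 0, 0)
  mx <- colMeans(X); my <- colMeans(Y)
  sigma2 <- (mean(rowSums(X^2)) + mean(rowSums(Y^2)) - 2 * sum(mx * my)) / 3
  floor2 <- max(sigma2, 1) * 1e-14
  Lold <- Inf
  flooredBefore <- FALSE
  converged <- FALSE
  iter <- 0L
  L <- NA_real_
  while (iter < maxIter) {
    iter <- iter + 1L
    Ty <- sweep(Y %*% t(Rm), 2, tv, "+")
    es <- cpp_cpd_estep(X, Ty, sigma2, outlierWeight)
    L <- es$L
    Np <- es$Np
    mux <- colSums(X * es$Pt1) / Np
    muy <- colSums(Y * es$P1) / Np
    A <- t(es$PX) %*% Y - Np * outer(mux, muy)
    sv <- svd(A)
    C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
    Rm <- sv$u %*% C %*% t(sv$v)
    tv <- as.numeric(mux - Rm %*% muy)
    xPx <- sum(es$Pt1 * rowSums(sweep(X, 2, mux)^2))
    yPy <- sum(es$P1 * rowSums(sweep(Y, 2, muy)^2))
    trAR <- sum(A * Rm)
    sigma2 <- (xPx - 2 * trAR + yPy) / (3 * Np)
    floored <- !is.finite(sigma2) || sigma2 < floor2
    if (floored) sigma2 <- floor2
    if (floored && isTRUE(flooredBefore)) {
      converged <- TRUE  # exact-match collapse of the mixture variance
      break
    }
    flooredBefore <- floored
    if (is.finite(Lold) && abs(Lold - L) < tol * (abs(L) + tol)) {
      converged <- TRUE
      break
    }
    Lold <- L
  }
  list(transform = rigidTransform(Rm, tv), objective = L, sigma2 = sigma2,
       iterations = iter, converged = converged)
}

# RMS nearest-point distance from cloud A to cloud B (mm)
rmsNearestPoint <- function(A, B) {
  sqrt(mean(cpp_nn_dist2(asPoints(A), asPoints(B))))
}

#' Select the template subject of a cohort
#'
#' Rigidly registers every mesh to every other with [cpdRigid()] and
#' computes the post-registration RMS nearest-point distance for each
#' ordered pair. The template is the subject with the lowest mean RMS to
#' all others (ties broken by lowest index); its mean RMS is the
#' cohort's template-fit statistic.
#'
#' @param meshes list of at least 2 [TriangleMesh-class] objects.
#' @param maxIter,tol passed to [cpdRigid()].
#' @return a list: `templateIndex`, `rmsTable` (n x n matrix, row =
#'   source, column = target, mm; diagonal 0), `meanRMS` (per subject),
#'   `templateRMS`.
#' @export
selectTemplate <- function(meshes, maxIter = 100, tol = 1e-6) {
  n <- length(meshes)
  if (n < 2) stop("template selection needs at least 2 meshes")
  pts <- lapply(meshes, asPoints)
  rms <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      reg <- cpdRigid(pts[[i]], pts[[j]], maxIter = maxIter, tol = tol)
      rms[i, j] <- rmsNearestPoint(applyTransform(reg$transform, pts[[i]]),
                                   pts[[j]])
    }
  }
  meanRMS <- rowSums(rms) / (n - 1)
  idx <- which.min(meanRMS)  # which.min takes the lowest index on ties
  list(templateIndex = idx, rmsTable = rms, meanRMS = meanRMS,
       templateRMS = meanRMS[idx])
}

#' Establish dense correspondence with a template
#'
#' Rigidly registers the template onto the target with [cpdRigid()] and
#' places each template vertex at its closest point on the target surface
#' (exact point-to-triangle projection). The result carries the
#' template's connectivity in the target's coordinate frame, so vertex i
#' marks the same anatomical location across subjects.
#'
#' @param template,target [TriangleMesh-class] objects.
#' @param maxIter,tol passed to [cpdRigid()].
#' @return a [TriangleMesh-class] with the template's faces, named after
#'   the target.
#' @export
establishCorrespondence <- function(template, target, maxIter = 100,
                                    tol = 1e-6) {
  Vt <- target@vertices
  FFt <- target@faces
  a <- Vt[FFt[, 1], , drop = FALSE]
  cr <- vcross(Vt[FFt[, 2], , drop = FALSE] - a,
               Vt[FFt[, 3], , drop = FALSE] - a)
  if (max(rowSums(cr^2)) <= 0)
    stop("target mesh has only zero-area faces")
  reg <- cpdRigid(template, target, maxIter = maxIter, tol = tol)
  P <- applyTransform(reg$transform, template@vertices)
  proj <- cpp_closest_on_mesh(P, Vt, FFt)
  triangleMesh(proj$points, template@faces, name = target@name,
               validate = FALSE)
}

vcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# closed-form rigid alignment of corresponded points Y onto X (Kabsch)
kabsch <- function(Y, X) {
  muy <- colMeans(Y); mux <- colMeans(X)
  A <- crossprod(sweep(X, 2, mux), sweep(Y, 2, muy))
  sv <- svd(A)
  C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
  Rm <- sv$u %*% C %*% t(sv$v)
  rigidTransform(Rm, as.numeric(mux - Rm %*% muy))
}

#' Generalized Procrustes alignment (rigid, no scaling)
#'
#' Iteratively aligns every corresponded mesh to the running consensus
#' mean with the closed-form rigid Procrustes fit, recomputing the mean
#' until it stabilises. Rotation and translation only: centroid size is
#' preserved exactly, so size variation stays in the shape model. The sum
#' of squared deviations from the consensus is non-increasing across
#' iterations.
#'
#' @param meshes list of corresponded [TriangleMesh-class] objects (same
#'   connectivity), or a [CorrespondedSet-class].
#' @param maxIter maximum alignment sweeps.
#' @param tol RMS change of the consensus mean (mm) declaring
#'   convergence.
#' @return a list: `meshes` (aligned), `mean` (consensus
#'   [TriangleMesh-class]), `transforms` (per subject, original ->
#'   aligned), `objective` (sum of squared deviations per iteration),
#'   `iterations`, `converged`.
#' @export
generalizedProcrustes <- function(meshes, maxIter = 100, tol = 1e-8) {
  if (is(meshes, "CorrespondedSet")) meshes <- meshes@meshes
  n <- length(meshes)
  if (n < 2) stop("generalized Procrustes needs at least 2 meshes")
  f0 <- meshes[[1]]@faces
  ok <- vapply(meshes, function(m) identical(dim(m@vertices),
                                             dim(meshes[[1]]@vertices)) &&
                 all(m@faces == f0), logical(1))
  if (!all(ok)) stop("meshes are not corresponded (connectivity differs)")

  orig <- lapply(meshes, function(m) m@vertices)
  M <- Reduce(`+`, orig) / n
  M <- sweep(M, 2, colMeans(M))
  aligned <- orig
  transforms <- replicate(n, rigidTransform(), simplify = FALSE)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    for (s in seq_len(n)) {
      tf <- kabsch(orig[[s]], M)
      transforms[[s]] <- tf
      aligned[[s]] <- applyTransform(tf, orig[[s]])
    }
    Mnew <- Reduce(`+`, aligned) / n
    Mnew <- sweep(Mnew, 2, colMeans(Mnew))
    objective <- c(objective,
                   sum(vapply(aligned,
                              function(V) sum((V - Mnew)^2), 0)))
    delta <- sqrt(mean((Mnew - M)^2))
    M <- Mnew
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  outMeshes <- mapply(function(m, V) {
    m@vertices <- V
    m
  }, meshes, aligned, SIMPLIFY = FALSE)
  list(meshes = outMeshes,
       mean = triangleMesh(M, f0, name = "consensus_mean",
                           validate = FALSE),
       transforms = transforms, objective = objective,
       iterations = iter, converged = converged)
}

#' Serialize a rigid transform as a homogeneous matrix
#'
#' Plain-text 4x4 homogeneous matrix, one row per line.
#'
#' @param transform a [RigidTransform-class].
#' @param path output text file.
#' @return `path` invisibly, or the read [RigidTransform-class].
#' @export
writeTransform <- function(transform, path) {
  H <- rbind(cbind(transform@rotation, transform@translation), c(0, 0, 0, 1))
  utils::write.table(format(H, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  H <- unname(as.matrix(utils::read.table(path)))
  rigidTransform(H[1:3, 1:3], H[1:3, 4])
}
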