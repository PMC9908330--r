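cohortMatrix <- function(meshes) {
  if (is(meshes, "CorrespondedSet")) meshes <- meshes@meshes
  n <- length(meshes)
  if (n < 2) stop("shape model fitting needs at least 2 meshes")
  nv <- nVertices(meshes[[1]])
  ok <- vapply(meshes, function(m) nVertices(m) == nv, logical(1))
  if (!all(ok)) stop("inconsistent vertex counts across the cohort")
  X <- t(vapply(meshes, function(m) flattenCoords(m@vertices),
                numeric(3 * nv)))
  list(X = X, faces = meshes[[1]]@faces, nv = nv)
}

# thin SVD PCA on n x p coordinates (dual form: never builds the p x p
# covariance); 1/(n-1) variance convention, largest-entry-positive signs
pcaFit <- function(X, nModes, faces, vertexIndices) {
  n <- nrow(X)
  kmax <- n - 1L
  if (identical(nModes, "all")) nModes <- kmax
  if (nModes > kmax)
    stop("requested ", nModes, " modes but at most nTrain - 1 = ", kmax,
         " are identifiable")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  sv <- svd(Xc)
  k <- min(as.integer(nModes), kmax, length(sv$d))
  Phi <- sv$v[, seq_len(k), drop = FALSE]
  lambda <- (sv$d[seq_len(k)]^2) / (n - 1)
  flip <- vapply(seq_len(k), function(j) {
    col <- Phi[, j]
    col[which.max(abs(col))] < 0
  }, logical(1))
  Phi[, flip] <- -Phi[, flip]
  new("ShapeModel", meanShape = xbar, modes = Phi, variances = lambda,
      totalVariance = sum(Xc^2) / (n - 1), nTrain = as.integer(n),
      faces = faces, vertexIndices = as.integer(vertexIndices))
}

#' Fit a (nonregion-based) statistical shape model
#'
#' PCA on the flattened nodal coordinates of aligned, corresponded
#' meshes: x = xbar + sum_i w_i Phi_i. Computed through the thin SVD of
#' the centred n x 3V coordinate matrix (the n x n dual of the
#' covariance eigendecomposition, exact and memory-light when 3V >> n).
#' Variances use the 1/(n - 1) convention, so +/-2 sqrt(lambda) spans
#' the usual +/-2SD of the training weights. At most n - 1 modes are
#' identifiable from n training shapes. Mode signs are fixed by making
#' each column's largest-magnitude entry positive.
#'
#' @param meshes list of corresponded aligned [TriangleMesh-class]
#'   objects, or a [CorrespondedSet-class].
#' @param nModes number of modes to retain, or "all" (= nTrain - 1).
#' @return a [ShapeModel-class].
#' @export
fitSSM <- function(meshes, nModes = "all") {
  cm <- cohortMatrix(meshes)
  pcaFit(cm$X, nModes, cm$faces, seq_len(cm$nv))
}

#' Fit a region-based statistical shape model
#'
#' One independent [ShapeModel-class] per region, each fit on that
#' region's vertex coordinates only, so each region's variation is
#' quantified independently of the rest of the surface.
#'
#' @param meshes corresponded aligned meshes (as in [fitSSM()]).
#' @param labeling a [RegionLabeling-class] on the shared connectivity.
#' @param nModes modes per region, or "all".
#' @return a [RegionalShapeModel-class].
#' @export
fitRSSM <- function(meshes, labeling, nModes = "all") {
  cm <- cohortMatrix(meshes)
  if (length(labeling@labels) != cm$nv)
    stop("labeling indexes ", length(labeling@labels),
         " vertices but the cohort has ", cm$nv)
  models <- lapply(seq_len(labeling@nRegions), function(r) {
    idx <- which(labeling@labels == r)
    if (length(idx) < 1) stop("region ", r, " has no vertices")
    cols <- as.vector(t(cbind(3 * idx - 2, 3 * idx - 1, 3 * idx)))
    faces <- if (length(idx) == cm$nv) cm$faces
    else matrix(integer(), 0, 3)
    pcaFit(cm$X[, cols, drop = FALSE], nModes, faces, idx)
  })
  new("RegionalShapeModel", labeling = labeling, models = models,
      faces = cm$faces)
}

#' @rdname ShapeModel-class
#' @export
setMethod("meanShape", "ShapeModel", function(x) x@meanShape)

#' @rdname ShapeModel-class
#' @export
setMethod("shapeModes", "ShapeModel", function(x) x@modes)

#' @rdname ShapeModel-class
#' @export
setMethod("modeVariances", "ShapeModel", function(x) x@variances)

#' @rdname ShapeModel-class
#' @export
setMethod("nModes", "ShapeModel", function(x) ncol(x@modes))

#' @rdname RegionalShapeModel-class
#' @param x a RegionalShapeModel.
#' @export
setMethod("nModes", "RegionalShapeModel",
          function(x) sum(vapply(x@models, nModes, 0L)))

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf("ShapeModel: %d training shapes, %d vertices, %d mode(s)\n",
              object@nTrain, length(object@vertexIndices),
              ncol(object@modes)))
  if (ncol(object@modes) > 0) {
    fr <- object@variances / object@totalVariance * 100
    cat(sprintf("  leading variance fractions (%%): %s\n",
                paste(sprintf("%.1f", utils::head(fr, 5)),
                      collapse = ", ")))
  }
})

setMethod("show", "RegionalShapeModel", function(object) {
  cat(sprintf("RegionalShapeModel: %d region(s)\n",
              object@labeling@nRegions))
  for (r in seq_along(object@models))
    cat(sprintf("  region %d: %d vertices, total variance %.4g mm^2\n", r,
                length(object@models[[r]]@vertexIndices),
                object@models[[r]]@totalVariance))
})

#' Mean shape as a mesh
#'
#' @param model a [ShapeModel-class] or [RegionalShapeModel-class].
#' @return a [TriangleMesh-class].
#' @export
meanMesh <- function(model) {
  if (is(model, "RegionalShapeModel")) {
    V <- regionalMeanVertices(model)
    return(triangleMesh(V, model@faces, name = "rssm_mean",
                        validate = FALSE))
  }
  triangleMesh(unflattenCoords(model@meanShape), model@faces,
               name = "mean", validate = FALSE)
}

regionalMeanVertices <- function(model) {
  nv <- length(model@labeling@labels)
  V <- matrix(0, nv, 3)
  for (m in model@models)
    V[m@vertexIndices, ] <- unflattenCoords(m@meanShape)
  V
}

#' Synthesize a shape from mode weights
#'
#' Evaluates x = xbar + sum_i w_i Phi_i and reshapes to the model's
#' connectivity.
#'
#' @param model a [ShapeModel-class] with a face list (whole-surface
#'   model).
#' @param weights numeric, at most one weight per mode; shorter vectors
#'   are zero-padded.
#' @return a [TriangleMesh-class].
#' @export
synthesizeShape <- function(model, weights = numeric()) {
  if (any(!is.finite(weights))) stop("weights must be finite")
  k <- ncol(model@modes)
  if (length(weights) > k)
    stop("got ", length(weights), " weights for ", k, " modes")
  x <- model@meanShape
  if (length(weights) > 0)
    x <- x + as.numeric(model@modes[, seq_along(weights), drop = FALSE] %*%
                          weights)
  if (nrow(model@faces) == 0)
    stop("model has no connectivity (regional sub-model); synthesize ",
         "through the RegionalShapeModel")
  triangleMesh(unflattenCoords(x), model@faces, name = "synthesized",
               validate = FALSE)
}

# a mode variance indistinguishable from floating-point dust, relative
# to the coordinate scale of the mean shape
isZeroVariance <- function(lam, meanShape) {
  lam <= 1e-12 * max(mean(meanShape^2), .Machine$double.eps)
}

#' @rdname sdModel
#' @export
setMethod("sdModel", "ShapeModel", function(model, mode, k) {
  if (mode < 1 || mode > ncol(model@modes))
    stop("mode index ", mode, " out of range")
  lam <- model@variances[mode]
  if (isZeroVariance(lam, model@meanShape)) {
    warning("mode ", mode, " has zero variance; returning the mean shape")
    m <- synthesizeShape(model, numeric())
  } else {
    w <- numeric(mode)
    w[mode] <- k * sqrt(lam)
    m <- synthesizeShape(model, w)
  }
  m@name <- sprintf("pc%d_%+gsd", mode, k)
  m
})

# pooled ordering of regional modes: sort all (region, local mode)
# variances non-increasing; ties keep region then local order
pooledModes <- function(model) {
  tab <- do.call(rbind, lapply(seq_along(model@models), function(r) {
    m <- model@models[[r]]
    if (ncol(m@modes) == 0) return(NULL)
    data.frame(region = r, localMode = seq_len(ncol(m@modes)),
               variance = m@variances)
  }))
  tab[order(-tab$variance, tab$region, tab$localMode), , drop = FALSE]
}

#' @rdname sdModel
#' @export
setMethod("sdModel", "RegionalShapeModel", function(model, mode, k) {
  pool <- pooledModes(model)
  if (mode < 1 || mode > nrow(pool))
    stop("pooled mode index ", mode, " out of range")
  r <- pool$region[mode]
  lm <- pool$localMode[mode]
  sub <- model@models[[r]]
  V <- regionalMeanVertices(model)
  lam <- sub@variances[lm]
  if (isZeroVariance(lam, sub@meanShape)) {
    warning("pooled mode ", mode, " has zero variance; returning the mean")
  } else {
    x <- sub@meanShape + k * sqrt(lam) * sub@modes[, lm]
    V[sub@vertexIndices, ] <- unflattenCoords(x)
  }
  triangleMesh(V, model@faces, name = sprintf("rssm_pc%d_%+gsd", mode, k),
               validate = FALSE)
})

#' Project a corresponded mesh onto a shape model
#'
#' Orthonormal projection w_i = Phi_i' (x - xbar): the inverse of
#' [synthesizeShape()] on the model's span.
#'
#' @param model a [ShapeModel-class].
#' @param mesh a [TriangleMesh-class] corresponded to the model's
#'   connectivity (or a vertex matrix).
#' @return numeric weight vector, one entry per mode.
#' @export
projectShape <- function(model, mesh) {
  V <- asPoints(mesh)
  nvFull <- if (is(mesh, "TriangleMesh")) nVertices(mesh) else nrow(V)
  if (max(model@vertexIndices) > nvFull)
    stop("mesh has ", nvFull, " vertices but the model indexes up to ",
         max(model@vertexIndices))
  x <- flattenCoords(V[model@vertexIndices, , drop = FALSE])
  if (length(x) != length(model@meanShape))
    stop("vertex count mismatch with the model")
  as.numeric(crossprod(model@modes, x - model@meanShape))
}

#' @rdname cumulativeVariance
#' @export
setMethod("cumulativeVariance", "ShapeModel", function(model) {
  fr <- model@variances / model@totalVariance
  data.frame(mode = seq_along(fr), variance = model@variances,
             fraction = fr, cumulative = cumsum(fr))
})

#' @rdname cumulativeVariance
#' @export
setMethod("cumulativeVariance", "RegionalShapeModel", function(model) {
  pool <- pooledModes(model)
  total <- sum(vapply(model@models, function(m) m@totalVariance, 0))
  fr <- pool$variance / total
  data.frame(mode = seq_len(nrow(pool)), region = pool$region,
             localMode = pool$localMode, variance = pool$variance,
             fraction = fr, cumulative = cumsum(fr))
})

#' Persist and reload a shape model
#'
#' Plain-text container: the mean shape as PLY (whole-surface models) or
#' CSV, modes and variances as CSV, metadata (training size, covered
#' vertex indices) as JSON.
#'
#' @param model a [ShapeModel-class].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly; `readShapeModel` returns the
#'   [ShapeModel-class].
#' @export
writeShapeModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(model@faces) > 0)
    writeMesh(meanMesh(model), file.path(dir, "mean.ply"))
  utils::write.table(format(unflattenCoords(model@meanShape), digits = 17),
                     file.path(dir, "mean_coords.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(format(model@modes, digits = 17),
                     file.path(dir, "modes.txt"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(nTrain = model@nTrain,
               totalVariance = model@totalVariance,
               variances = model@variances,
               vertexIndices = model@vertexIndices,
               faces = as.vector(t(model@faces)))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeShapeModel
#' @export
readShapeModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  mean <- as.matrix(utils::read.table(file.path(dir, "mean_coords.txt")))
  modes <- as.matrix(utils::read.table(file.path(dir, "modes.txt")))
  dimnames(modes) <- NULL
  faces <- matrix(as.integer(meta$faces), ncol = 3, byrow = TRUE)
  new("ShapeModel", meanShape = flattenCoords(mean), modes = modes,
      variances = as.numeric(meta$variances),
      totalVariance = as.numeric(meta$totalVariance),
      nTrain = as.integer(meta$nTrain), faces = faces,
      vertexIndices = as.integer(meta$vertexIndices))
}
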