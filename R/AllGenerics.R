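#' @rdname TriangleMesh-class
#' @param x,object an object.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshName", function(x) standardGeneric("meshName"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname RigidTransform-class
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname RigidTransform-class
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' Apply a rigid transform
#'
#' Maps points (or a mesh's vertices) y to R y + t.
#'
#' @param transform a [RigidTransform-class].
#' @param x a numeric n x 3 matrix of points or a [TriangleMesh-class].
#' @return an object of the same kind as `x`.
#' @export
setGeneric("applyTransform",
           function(transform, x) standardGeneric("applyTransform"))

#' @rdname CurvatureField-class
#' @export
setGeneric("curvatureValues", function(x) standardGeneric("curvatureValues"))

#' @rdname CurvatureField-class
#' @export
setGeneric("vertexAreas", function(x) standardGeneric("vertexAreas"))

#' @rdname RegionLabeling-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname RegionLabeling-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname ShapeModel-class
#' @export
setGeneric("meanShape", function(x) standardGeneric("meanShape"))

#' @rdname ShapeModel-class
#' @export
setGeneric("shapeModes", function(x) standardGeneric("shapeModes"))

#' @rdname ShapeModel-class
#' @export
setGeneric("modeVariances", function(x) standardGeneric("modeVariances"))

#' @rdname ShapeModel-class
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))

#' Per-mode and cumulative variance fractions
#'
#' For a [ShapeModel-class], fractions are relative to the model's total
#' training variance. For a [RegionalShapeModel-class] all regional modes
#' are pooled, sorted by variance, and fractions are taken relative to the
#' total pooled variance, giving one aggregate curve for the region-based
#' model.
#'
#' @param model a fitted shape model.
#' @return a data.frame with columns `mode`, `variance`, `fraction`,
#'   `cumulative` (and `region`, `localMode` for the regional form).
#' @export
setGeneric("cumulativeVariance",
           function(model) standardGeneric("cumulativeVariance"))

#' Synthesize the mean +/- k SD shape of one mode
#'
#' Sets weight k * sqrt(lambda_i) on the chosen mode and 0 elsewhere;
#' k = +/-2 gives the conventional +/-2SD shapes. For a regional model the
#' pooled mode ordering is used: mode i is the i-th largest regional mode,
#' its region is synthesized at +/-k SD and all other regions stay at the
#' mean.
#'
#' @param model a fitted shape model.
#' @param mode 1-based mode index.
#' @param k signed SD multiple.
#' @return a [TriangleMesh-class]. If the mode variance is zero the mean
#'   shape is returned with a warning.
#' @export
setGeneric("sdModel", function(model, mode, k) standardGeneric("sdModel"))
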