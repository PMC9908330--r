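#' @useDynLib rssm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm sd cor var
#' @importFrom utils read.csv write.csv
NULL

#' TriangleMesh: a triangulated surface
#'
#' Vertices are 3D points in millimetres; faces are 1-based vertex-index
#' triples. Vertex order is semantic: downstream shape models identify
#' vertex i across subjects (dense correspondence), so readers and all
#' geometric operations preserve it.
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot name free-text identifier.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", name = "character"),
  prototype(vertices = matrix(numeric(), 0, 3),
            faces = matrix(integer(), 0, 3), name = ""))

# structural validity only (cheap, Bioconductor-style); the full
# geometric invariants are checked by validateMesh() and enforced by the
# triangleMesh() constructor, so deliberately broken meshes can still be
# represented for inspection
setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3) return("vertices must have 3 columns")
  if (ncol(object@faces) != 3) return("faces must have 3 columns")
  if (!is.double(object@vertices)) return("vertices must be numeric")
  if (!is.integer(object@faces)) return("faces must be integer")
  TRUE
})

#' RigidTransform: rotation + translation in 3D
#'
#' Maps a point cloud Y onto R Y^T + t. Rotation is proper orthonormal
#' (det +1); translation is in millimetres.
#'
#' @slot rotation 3x3 rotation matrix.
#' @slot translation length-3 numeric (mm).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (length(object@translation) != 3) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation is not orthonormal (tol 1e-9)")
  if (abs(det(R) - 1) > 1e-9) return("rotation determinant is not +1")
  TRUE
})

#' CurvatureField: per-vertex discrete Gaussian curvature
#'
#' Angle-deficit Gaussian curvature (1/mm^2) with the mixed vertex areas
#' (mm^2) it was normalised by. For a closed mesh the area-weighted sum
#' satisfies Gauss-Bonnet: sum(values * areas) = 2 * pi * chi.
#'
#' @slot values numeric, curvature per vertex (1/mm^2).
#' @slot areas numeric, mixed area per vertex (mm^2), all positive.
#' @slot meshName identifier of the mesh the field indexes.
#' @export
setClass("CurvatureField",
  representation(values = "numeric", areas = "numeric", meshName = "character"),
  prototype(values = numeric(), areas = numeric(), meshName = ""))

setValidity("CurvatureField", function(object) {
  if (length(object@values) != length(object@areas))
    return("values and areas must have equal length")
  if (length(object@areas) && any(!is.finite(object@areas) | object@areas <= 0))
    return("all vertex areas must be positive and finite")
  TRUE
})

#' RegionLabeling: curvature-sign surface partition
#'
#' Per-vertex region ids in 1..R. In the default two-region configuration
#' region 1 holds non-positive (concave/saddle) smoothed curvature and
#' region 2 positive (convex). A single-sign surface collapses to R = 1
#' with \code{singleSign = TRUE}.
#'
#' @slot labels integer vector of region ids (1..R), one per vertex.
#' @slot nRegions number of regions R.
#' @slot smoothedField the smoothed curvature the labels were cut from.
#' @slot singleSign logical flag: all vertices had one curvature sign.
#' @export
setClass("RegionLabeling",
  representation(labels = "integer", nRegions = "integer",
                 smoothedField = "numeric", singleSign = "logical"),
  prototype(labels = integer(), nRegions = 0L, smoothedField = numeric(),
            singleSign = FALSE))

setValidity("RegionLabeling", function(object) {
  R <- object@nRegions
  if (length(object@labels) == 0) return(TRUE)
  if (any(object@labels < 1L | object@labels > R))
    return("labels must lie in 1..nRegions")
  if (!all(seq_len(R) %in% object@labels))
    return("every region id in 1..nRegions must be used")
  TRUE
})

#' CorrespondedSet: a cohort sharing one connectivity
#'
#' All meshes have identical face lists; vertex i is the same anatomical
#' location on every subject. \code{rmsToTemplate} is the post-registration
#' RMS nearest-point distance of each subject to the template (mm).
#'
#' @slot meshes list of TriangleMesh with identical connectivity.
#' @slot templateIndex which subject served as template (1-based).
#' @slot rmsToTemplate per-subject RMS distance to the template (mm).
#' @export
setClass("CorrespondedSet",
  representation(meshes = "list", templateIndex = "integer",
                 rmsToTemplate = "numeric"),
  prototype(meshes = list(), templateIndex = 1L, rmsToTemplate = numeric()))

setValidity("CorrespondedSet", function(object) {
  if (length(object@meshes) == 0) return(TRUE)
  f0 <- object@meshes[[1]]@faces
  same <- vapply(object@meshes, function(m) identical(dim(m@faces), dim(f0)) &&
                   all(m@faces == f0), logical(1))
  if (!all(same)) return("all meshes must share one face list")
  if (object@templateIndex < 1 || object@templateIndex > length(object@meshes))
    return("templateIndex out of range")
  TRUE
})

#' PopulationConfig: parameters of the synthetic bone cohort
#'
#' @slot nSubjects cohort size (>= 3).
#' @slot modeSds named numeric: sd of each latent mode weight. Names are
#'   size (log-scale factor), width (radial factor), torsion (degrees),
#'   bending (degrees).
#' @slot vertexNoiseSd isotropic per-coordinate noise sd (mm).
#' @slot misalignRotationSd sd of the random misalignment rotation angle
#'   (degrees).
#' @slot misalignTranslationSd sd of each misalignment translation
#'   component (mm).
#' @slot templateResolution integer c(axial, circumferential) vertex counts.
#' @slot seed RNG seed making the cohort reproducible.
#' @export
setClass("PopulationConfig",
  representation(nSubjects = "integer", modeSds = "numeric",
                 vertexNoiseSd = "numeric", misalignRotationSd = "numeric",
                 misalignTranslationSd = "numeric",
                 templateResolution = "integer", seed = "integer"),
  prototype(nSubjects = 31L,
            modeSds = c(size = 0.05, width = 0.05, torsion = 6, bending = 4),
            vertexNoiseSd = 0.05, misalignRotationSd = 10,
            misalignTranslationSd = 5, templateResolution = c(24L, 16L),
            seed = 20230001L))

setValidity("PopulationConfig", function(object) {
  if (object@nSubjects < 3L) return("nSubjects must be >= 3")
  if (!all(sort(names(object@modeSds)) ==
             sort(c("size", "width", "torsion", "bending"))))
    return("modeSds must be named size, width, torsion, bending")
  if (any(object@modeSds < 0) || object@vertexNoiseSd < 0 ||
      object@misalignRotationSd < 0 || object@misalignTranslationSd < 0)
    return("all standard deviations must be >= 0")
  if (length(object@templateResolution) != 2 ||
      any(object@templateResolution < 8L))
    return("templateResolution must be two counts >= 8")
  TRUE
})

#' PopulationSample: synthetic cohort with known ground truth
#'
#' @slot meshes list of TriangleMesh, vertex-corresponded by construction.
#' @slot latentWeights numeric matrix, subjects x modes (size, width,
#'   torsion, bending): the latent weights actually drawn.
#' @slot trueTransforms list of RigidTransform misalignments applied.
#' @slot template the noise-free mean-shape template.
#' @slot config the PopulationConfig that generated the sample.
#' @export
setClass("PopulationSample",
  representation(meshes = "list", latentWeights = "matrix",
                 trueTransforms = "list", template = "TriangleMesh",
                 config = "PopulationConfig"))

setValidity("PopulationSample", function(object) {
  n <- length(object@meshes)
  if (nrow(object@latentWeights) != n)
    return("latentWeights must have one row per subject")
  if (length(object@trueTransforms) != n)
    return("trueTransforms must have one entry per subject")
  f0 <- object@template@faces
  same <- vapply(object@meshes, function(m) all(m@faces == f0), logical(1))
  if (!all(same)) return("all meshes must share the template connectivity")
  TRUE
})

#' ShapeModel: a PCA model of corresponded shape
#'
#' The linear model x = xbar + sum_i w_i Phi_i over flattened vertex
#' coordinates (vertex-major: x1,y1,z1,x2,...). Modes are orthonormal and
#' ordered by non-increasing variance; at most nTrain - 1 modes exist.
#'
#' @slot meanShape numeric length 3V, the mean coordinates (mm).
#' @slot modes matrix 3V x k, orthonormal columns Phi_i.
#' @slot variances numeric length k, training-weight variance per mode
#'   (mm^2), non-increasing.
#' @slot totalVariance total coordinate variance of the training set
#'   (mm^2); equals sum(variances) when all nTrain - 1 modes are kept.
#' @slot nTrain training-set size.
#' @slot faces shared connectivity (may be empty for regional sub-models).
#' @slot vertexIndices indices of the full mesh's vertices this model
#'   covers (seq_len(V) for a whole-surface model).
#' @export
setClass("ShapeModel",
  representation(meanShape = "numeric", modes = "matrix",
                 variances = "numeric", totalVariance = "numeric",
                 nTrain = "integer", faces = "matrix",
                 vertexIndices = "integer"))

setValidity("ShapeModel", function(object) {
  k <- ncol(object@modes)
  if (length(object@variances) != k)
    return("one variance per mode required")
  if (k > 0) {
    if (k > object@nTrain - 1L)
      return("mode count exceeds nTrain - 1")
    g <- crossprod(object@modes)
    if (max(abs(g - diag(k))) > 1e-9)
      return("modes are not orthonormal (tol 1e-9)")
    if (is.unsorted(rev(object@variances)))
      return("variances must be non-increasing")
  }
  if (length(object@meanShape) != 3L * length(object@vertexIndices))
    return("meanShape length must be 3 * number of covered vertices")
  TRUE
})

#' RegionalShapeModel: independent PCA models per surface region
#'
#' One ShapeModel per curvature region, each fit on that region's vertex
#' coordinates only; the regions partition the full vertex set.
#'
#' @slot labeling the RegionLabeling defining the partition.
#' @slot models list of ShapeModel, one per region id.
#' @slot faces the full-surface connectivity (for whole-bone synthesis).
#' @export
setClass("RegionalShapeModel",
  representation(labeling = "RegionLabeling", models = "list",
                 faces = "matrix"))

setValidity("RegionalShapeModel", function(object) {
  R <- object@labeling@nRegions
  if (length(object@models) != R)
    return("one ShapeModel per region required")
  cov <- sort(unlist(lapply(object@models, function(m) m@vertexIndices)))
  if (!identical(cov, seq_along(object@labeling@labels)))
    return("regional vertex index sets must partition the vertex set")
  TRUE
})

#' DistanceMap: per-vertex distances between two shapes
#'
#' For corresponded input (same connectivity) the distance is the
#' per-vertex Euclidean distance, which is symmetric; otherwise the
#' nearest-point-on-surface distance is used and \code{corresponded} is
#' FALSE.
#'
#' @slot distances per-vertex distance (mm), all >= 0.
#' @slot sourceName,targetName identifiers of the two meshes.
#' @slot corresponded logical: per-vertex (TRUE) or nearest-surface mode.
#' @export
setClass("DistanceMap",
  representation(distances = "numeric", sourceName = "character",
                 targetName = "character", corresponded = "logical"),
  prototype(distances = numeric(), sourceName = "", targetName = "",
            corresponded = TRUE))

setValidity("DistanceMap", function(object) {
  if (length(object@distances) && any(object@distances < 0))
    return("distances must be non-negative")
  TRUE
})

#' ComparisonReport: the pipeline's end-to-end data products
#'
#' Holds the cumulative-variance comparison between the whole-surface
#' model (nrSSM) and the region-based model (rSSM), Gaussian-curvature
#' summaries of the +/-2SD shapes, distance-map summaries per mode, and
#' run provenance (config, seed, template index, template RMS).
#'
#' @slot cumulativeVariance data.frame: component, nrSSM and rSSM
#'   cumulative variance percentages.
#' @slot curvatureTable data.frame of curvature summaries per model, mode,
#'   SD sign and scope (whole surface / perturbed region).
#' @slot distanceTable data.frame of distance-map summaries per model,
#'   mode and mesh pair.
#' @slot templateIndex subject chosen as template.
#' @slot templateRMS mean RMS (mm) of the chosen template to the cohort.
#' @slot provenance list: config used, seed, package version.
#' @export
setClass("ComparisonReport",
  representation(cumulativeVariance = "data.frame",
                 curvatureTable = "data.frame",
                 distanceTable = "data.frame",
                 templateIndex = "integer", templateRMS = "numeric",
                 provenance = "list"))
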