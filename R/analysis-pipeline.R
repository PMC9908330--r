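#' Per-vertex distance map between two shapes
#'
#' For meshes sharing one connectivity the distance is the per-vertex
#' Euclidean distance (symmetric, exactly reproducible). Otherwise each
#' vertex of `a` is measured to its closest point on the surface of `b`
#' and the map is flagged non-corresponded.
#'
#' @param a,b [TriangleMesh-class] objects.
#' @return a [DistanceMap-class].
#' @export
distanceMap <- function(a, b) {
  if (nVertices(a) == 0 || nVertices(b) == 0) stop("empty mesh")
  if (nVertices(a) == nVertices(b) && all(a@faces == b@faces)) {
    d <- sqrt(rowSums((a@vertices - b@vertices)^2))
    corr <- TRUE
  } else {
    d <- cpp_closest_on_mesh(a@vertices, b@vertices, b@faces)$dist
    corr <- FALSE
  }
  new("DistanceMap", distances = d, sourceName = a@name,
      targetName = b@name, corresponded = corr)
}

#' Summary statistics of a distance map
#'
#' @param map a [DistanceMap-class].
#' @return named numeric: mean, max, rms (mm), recomputed from the
#'   per-vertex distances.
#' @export
distanceSummary <- function(map) {
  c(mean = mean(map@distances), max = max(map@distances),
    rms = sqrt(mean(map@distances^2)))
}

setMethod("show", "DistanceMap", function(object) {
  s <- distanceSummary(object)
  cat(sprintf("DistanceMap '%s' -> '%s'%s: mean %.4g, max %.4g, rms %.4g mm\n",
              object@sourceName, object@targetName,
              if (object@corresponded) "" else " (nearest-surface)",
              s["mean"], s["max"], s["rms"]))
})

#' Compare cumulative variance of the two model types
#'
#' Tabulates the cumulative variance percentage against component count
#' for the whole-surface model and the region-based model (regional modes
#' pooled and sorted by variance, fractions relative to total pooled
#' variance).
#'
#' @param nr a [ShapeModel-class] (nonregion-based).
#' @param r a [RegionalShapeModel-class] fit on the same cohort.
#' @param maxComponents table length.
#' @return data.frame: `component`, `nrSSM`, `rSSM` (cumulative %).
#' @export
compareCumulativeVariance <- function(nr, r, maxComponents = 10) {
  cvn <- cumulativeVariance(nr)$cumulative
  cvr <- cumulativeVariance(r)$cumulative
  at <- function(cv, i) cv[pmin(i, length(cv))]
  i <- seq_len(maxComponents)
  data.frame(component = i, nrSSM = 100 * at(cvn, i),
             rSSM = 100 * at(cvr, i))
}

#' Gaussian-curvature comparison of the +/-2SD shapes
#'
#' For each requested mode and SD sign, synthesizes the extreme shape of
#' both model types ([sdModel()]; the regional model perturbs its pooled
#' mode's region and keeps the others at the mean) and tabulates
#' area-weighted curvature summaries — over the whole surface for both
#' models, and additionally over the perturbed region for the regional
#' model.
#'
#' @param nr a [ShapeModel-class].
#' @param r a [RegionalShapeModel-class].
#' @param modes mode indices to synthesize.
#' @param k absolute SD multiple (both signs are tabulated).
#' @return data.frame: `model`, `mode`, `sd`, `scope`, `region`,
#'   curvature summary columns.
#' @export
curvatureComparison <- function(nr, r, modes = 1:4, k = 2) {
  pool <- pooledModes(r)
  rows <- list()
  for (m in modes) {
    for (s in c(-k, k)) {
      cs <- curvatureSummary(sdModel(nr, m, s))[1, ]
      rows[[length(rows) + 1]] <-
        cbind(data.frame(model = "nrSSM", mode = m, sd = s,
                         scope = "whole", region = NA_integer_), cs[-1])
      mesh <- sdModel(r, m, s)
      reg <- pool$region[m]
      csr <- curvatureSummary(mesh, r@labeling)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(model = "rSSM", mode = m, sd = s,
                         scope = "whole", region = NA_integer_),
              csr[1, -1])
      rows[[length(rows) + 1]] <-
        cbind(data.frame(model = "rSSM", mode = m, sd = s,
                         scope = "region", region = reg),
              csr[1 + reg, -1])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a pipeline config file
#'
#' YAML (or JSON) with sections: `synthetic` (keys of
#' [populationConfig()]) or `input` (`dir` of mesh files);
#' `registration` (`maxIter`, `tol`); `regions` (`smoothingRounds`,
#' `minComponentFrac`); `model` (`nModes`); `report` (`modes`,
#' `maxComponents`). All sections optional except one of
#' synthetic/input.
#'
#' @param path config file.
#' @return a list understood by [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$synthetic) && is.null(cfg$input))
    stop("pipeline config needs a 'synthetic' or 'input' section")
  if (!is.null(cfg$synthetic)) {
    if (!is.null(cfg$synthetic$modeSds))
      cfg$synthetic$modeSds <- unlist(cfg$synthetic$modeSds)
    cfg$synthetic <- do.call(populationConfig, cfg$synthetic)
  }
  cfg
}

pipelineDefaults <- function() {
  list(registration = list(maxIter = 100, tol = 1e-6),
       regions = list(smoothingRounds = 3, minComponentFrac = 0.01),
       model = list(nModes = "all"),
       report = list(modes = 4, maxComponents = 10),
       correspondence = "project", skipGPA = FALSE)
}

#' Run the full model-comparison pipeline
#'
#' End-to-end orchestration: load or generate the cohort, select the
#' template by all-pairs rigid registration, establish dense
#' correspondence, align with generalized Procrustes, partition the
#' template by Gaussian-curvature sign, transfer the labels, fit the
#' whole-surface and region-based shape models, synthesize the +/-2SD
#' shape of each reported mode, and tabulate distance maps, the
#' cumulative-variance comparison and the curvature comparison. Fully
#' reproducible: the same config produces an identical report. Stage
#' timings go to the message stream (and `log.txt` under `outDir`), never
#' into the report.
#'
#' @param config a [PopulationConfig-class], a config file path (see
#'   [readPipelineConfig()]), or an equivalent list.
#' @param outDir optional directory for artifacts: mean and +/-2SD
#'   meshes (PLY), per-vertex curvature/label CSV, report tables (CSV),
#'   `report.json`, `log.txt`.
#' @param correspondence "project" (rigid registration + closest-point
#'   projection of template vertices) or "identity" (trust shared
#'   connectivity; only valid for cohorts corresponded by construction).
#' @param skipGPA skip the Procrustes stage and model the corresponded
#'   meshes as registered to the template.
#' @param verbose emit stage messages.
#' @return a [ComparisonReport-class].
#' @export
runPipeline <- function(config, outDir = NULL,
                        correspondence = NULL, skipGPA = NULL,
                        verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (is(config, "PopulationConfig")) config <- list(synthetic = config)
  opts <- utils::modifyList(pipelineDefaults(),
                            config[setdiff(names(config),
                                           c("synthetic", "input"))])
  if (!is.null(correspondence)) opts$correspondence <- correspondence
  if (!is.null(skipGPA)) opts$skipGPA <- skipGPA
  opts$correspondence <- match.arg(opts$correspondence,
                                   c("project", "identity"))
  logLines <- character()
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    line <- sprintf("[%7.2fs] %-22s done in %.2fs", ts - t0, name,
                    proc.time()[["elapsed"]] - ts)
    if (verbose) message(line)
    logLines <<- c(logLines, line)
    res
  }

  meshes <- stage("load/generate", {
    if (!is.null(config$synthetic)) samplePopulation(config$synthetic)@meshes
    else {
      files <- sort(list.files(config$input$dir,
                               pattern = "\\.(ply|stl|obj)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) < 3) stop("need at least 3 mesh files in ",
                                  config$input$dir)
      lapply(files, readMesh)
    }
  })
  reg <- opts$registration
  sel <- stage("select_template",
               selectTemplate(meshes, maxIter = reg$maxIter,
                              tol = reg$tol))
  tidx <- sel$templateIndex
  logLines <- c(logLines,
                sprintf("template: subject %d, mean RMS %.4f mm", tidx,
                        sel$templateRMS))

  corr <- stage("correspondence", {
    if (opts$correspondence == "identity") {
      f0 <- meshes[[tidx]]@faces
      same <- vapply(meshes, function(m) all(dim(m@faces) == dim(f0)) &&
                       all(m@faces == f0), logical(1))
      if (!all(same))
        stop("identity correspondence requires shared connectivity")
      meshes
    } else {
      lapply(seq_along(meshes), function(j) {
        if (j == tidx) return(meshes[[j]])
        establishCorrespondence(meshes[[tidx]], meshes[[j]],
                                maxIter = reg$maxIter, tol = reg$tol)
      })
    }
  })
  cset <- new("CorrespondedSet", meshes = corr, templateIndex = tidx,
              rmsToTemplate = sel$rmsTable[tidx, ])

  aligned <- stage("procrustes", {
    if (opts$skipGPA) corr else generalizedProcrustes(corr)$meshes
  })

  labeling <- stage("curvature_regions", {
    tm <- aligned[[tidx]]
    partitionRegions(gaussianCurvature(tm), tm,
                     smoothingRounds = opts$regions$smoothingRounds,
                     minComponentFrac = opts$regions$minComponentFrac)
  })
  subjectLabels <- transferLabels(labeling, aligned)

  nrModel <- stage("fit_nrssm", fitSSM(aligned, nModes = opts$model$nModes))
  rModel <- stage("fit_rssm",
                  fitRSSM(aligned, labeling, nModes = opts$model$nModes))

  nRep <- min(opts$report$modes, nModes(nrModel), nModes(rModel))
  sdMeshes <- stage("sd_models", {
    out <- list()
    for (m in seq_len(nRep)) {
      out[[sprintf("nrSSM_pc%d_-2sd", m)]] <- sdModel(nrModel, m, -2)
      out[[sprintf("nrSSM_pc%d_+2sd", m)]] <- sdModel(nrModel, m, 2)
      out[[sprintf("rSSM_pc%d_-2sd", m)]] <- sdModel(rModel, m, -2)
      out[[sprintf("rSSM_pc%d_+2sd", m)]] <- sdModel(rModel, m, 2)
    }
    out
  })

  distTab <- stage("distance_maps", {
    means <- list(nrSSM = meanMesh(nrModel), rSSM = meanMesh(rModel))
    rows <- list()
    for (mod in c("nrSSM", "rSSM")) {
      for (m in seq_len(nRep)) {
        lo <- sdMeshes[[sprintf("%s_pc%d_-2sd", mod, m)]]
        hi <- sdMeshes[[sprintf("%s_pc%d_+2sd", mod, m)]]
        pairs <- list(`mean_vs_-2sd` = distanceMap(means[[mod]], lo),
                      `mean_vs_+2sd` = distanceMap(means[[mod]], hi),
                      `-2sd_vs_+2sd` = distanceMap(lo, hi))
        for (p in names(pairs)) {
          s <- distanceSummary(pairs[[p]])
          rows[[length(rows) + 1]] <-
            data.frame(model = mod, mode = m, pair = p,
                       mean = s["mean"], max = s["max"], rms = s["rms"])
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  cumTab <- stage("cumulative_variance",
                  compareCumulativeVariance(nrModel, rModel,
                                            opts$report$maxComponents))
  curvTab <- stage("curvature_comparison",
                   curvatureComparison(nrModel, rModel,
                                       modes = seq_len(nRep)))

  provenance <- list(
    config = if (!is.null(config$synthetic))
      list(synthetic = configAsList(config$synthetic)) else config["input"],
    options = opts,
    seed = if (!is.null(config$synthetic)) config$synthetic@seed else NA,
    package = as.character(utils::packageVersion("rssm")))
  report <- new("ComparisonReport", cumulativeVariance = cumTab,
                curvatureTable = curvTab, distanceTable = distTab,
                templateIndex = tidx, templateRMS = sel$templateRMS,
                provenance = provenance)

  if (!is.null(outDir)) {
    stage("write_artifacts", {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      writeMesh(meanMesh(nrModel), file.path(outDir, "nrSSM_mean.ply"))
      writeMesh(meanMesh(rModel), file.path(outDir, "rSSM_mean.ply"))
      for (nm in names(sdMeshes))
        writeMesh(sdMeshes[[nm]], file.path(outDir, paste0(nm, ".ply")))
      writeCurvatureCSV(gaussianCurvature(aligned[[tidx]]), labeling,
                        file.path(outDir, "template_curvature.csv"))
      write.csv(as.data.frame(sel$rmsTable),
                file.path(outDir, "registration_rms.csv"),
                row.names = FALSE)
      write.csv(cumTab, file.path(outDir, "cumulative_variance.csv"),
                row.names = FALSE)
      write.csv(curvTab, file.path(outDir, "curvature_comparison.csv"),
                row.names = FALSE)
      write.csv(distTab, file.path(outDir, "distance_maps.csv"),
                row.names = FALSE)
      writeReport(report, file.path(outDir, "report.json"))
      invisible(NULL)
    })
    writeLines(logLines, file.path(outDir, "log.txt"))
  }
  report
}

configAsList <- function(config) {
  list(nSubjects = config@nSubjects, modeSds = as.list(config@modeSds),
       vertexNoiseSd = config@vertexNoiseSd,
       misalignRotationSd = config@misalignRotationSd,
       misalignTranslationSd = config@misalignTranslationSd,
       templateResolution = config@templateResolution,
       seed = config@seed)
}

#' Write a comparison report as JSON
#'
#' @param report a [ComparisonReport-class].
#' @param path output .json file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(
    list(cumulativeVariance = report@cumulativeVariance,
         curvatureTable = report@curvatureTable,
         distanceTable = report@distanceTable,
         templateIndex = report@templateIndex,
         templateRMS = report@templateRMS,
         provenance = report@provenance),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns",
    na = "null")
  invisible(path)
}

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n")
  cat(sprintf("  template: subject %d (mean RMS %.4f mm)\n",
              object@templateIndex, object@templateRMS))
  cat("  cumulative variance (%):\n")
  print(utils::head(object@cumulativeVariance, 6), row.names = FALSE)
})
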