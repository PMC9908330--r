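test_that("distance maps are exact on corresponded meshes", {
  tm <- buildTemplate(c(10, 8))
  expect_equal(max(distanceMap(tm, tm)@distances), 0)
  shifted <- triangleMesh(sweep(vertices(tm), 2, c(1, 0, 0), "+"),
                          faces(tm), name = "shifted")
  dm <- distanceMap(tm, shifted)
  expect_true(dm@corresponded)
  expect_equal(dm@distances, rep(1, nVertices(tm)), tolerance = 1e-12)
  s <- distanceSummary(dm)
  expect_equal(unname(s), c(1, 1, 1))
  expect_error(distanceMap(new("TriangleMesh"), tm), "empty")
})

test_that("non-corresponded distance maps use the nearest surface", {
  tm <- icosphereMesh(2, 5)
  other <- icosphereMesh(1, 5)  # different connectivity, same sphere
  dm <- distanceMap(tm, other)
  expect_false(dm@corresponded)
  expect_lt(max(dm@distances), 0.5)  # within discretization of the sphere
})

test_that("distance between mean and +2SD matches the mode field", {
  set.seed(31)
  base <- icosphereMesh(2, 10)
  p <- 3 * nVertices(base)
  d <- rnorm(p); d <- d / sqrt(sum(d^2))
  cohort <- linearCohort(base, matrix(d, ncol = 1),
                         matrix(rnorm(200, sd = 0.5), ncol = 1))
  ssm <- fitSSM(cohort)
  dm <- distanceMap(meanMesh(ssm), sdModel(ssm, 1, 2))
  # oracle: 2 sqrt(lambda) times the per-vertex norm of the mode column
  phi <- matrix(shapeModes(ssm)[, 1], ncol = 3, byrow = TRUE)
  oracle <- 2 * sqrt(modeVariances(ssm)[1]) * sqrt(rowSums(phi^2))
  expect_equal(dm@distances, oracle, tolerance = 1e-10)
})

test_that("cumulative-variance comparison reduces and saturates", {
  cfg <- populationConfig(nSubjects = 8, seed = 41,
                          misalignRotationSd = 0, misalignTranslationSd = 0)
  meshes <- samplePopulation(cfg)@meshes
  ssm <- fitSSM(meshes)
  nv <- nVertices(meshes[[1]])
  lab1 <- new("RegionLabeling", labels = rep(1L, nv), nRegions = 1L,
              smoothedField = numeric(nv), singleSign = TRUE)
  tab <- compareCumulativeVariance(ssm, fitRSSM(meshes, lab1), 10)
  expect_equal(tab$nrSSM, tab$rSSM, tolerance = 1e-12)
  expect_true(all(diff(tab$nrSSM) >= -1e-12))
  expect_equal(tab$nrSSM[10], 100, tolerance = 1e-9)
})

test_that("rSSM cumulative curve dominates for localized variation", {
  set.seed(42)
  tm <- buildTemplate()
  lab <- partitionRegions(gaussianCurvature(tm), tm)
  idx2 <- which(regionLabels(lab) == 2L)
  cols2 <- as.vector(t(cbind(3 * idx2 - 2, 3 * idx2 - 1, 3 * idx2)))
  K <- 5
  D <- matrix(0, 3 * nVertices(tm), K)
  D[cols2, ] <- rnorm(length(cols2) * K)
  D <- qr.Q(qr(D))[, 1:K]
  W <- sapply(c(1, 0.7, 0.5, 0.3, 0.2), function(s) rnorm(25, sd = s))
  cohort <- linearCohort(tm, D, W)
  tab <- compareCumulativeVariance(fitSSM(cohort), fitRSSM(cohort, lab), 10)
  expect_true(all(tab$rSSM >= tab$nrSSM - 1e-9))
})

test_that("curvature comparison honours its reduction identities", {
  cfg <- populationConfig(nSubjects = 8, seed = 43,
                          misalignRotationSd = 0, misalignTranslationSd = 0)
  meshes <- samplePopulation(cfg)@meshes
  ssm <- fitSSM(meshes)
  nv <- nVertices(meshes[[1]])
  lab1 <- new("RegionLabeling", labels = rep(1L, nv), nRegions = 1L,
              smoothedField = numeric(nv), singleSign = TRUE)
  tab <- curvatureComparison(ssm, fitRSSM(meshes, lab1), modes = 1:2)
  whole <- tab[tab$scope == "whole", ]
  for (m in 1:2) for (s in c(-2, 2)) {
    a <- whole[whole$model == "nrSSM" & whole$mode == m & whole$sd == s, ]
    b <- whole[whole$model == "rSSM" & whole$mode == m & whole$sd == s, ]
    expect_equal(a$meanK, b$meanK, tolerance = 1e-10)
    expect_equal(a$meanAbsK, b$meanAbsK, tolerance = 1e-10)
  }
})

test_that("zero-variance modes compare as the mean model", {
  tm <- buildTemplate(c(10, 8))
  meshes <- list(tm, tm, tm)
  ssm <- fitSSM(meshes)
  nv <- nVertices(tm)
  lab1 <- new("RegionLabeling", labels = rep(1L, nv), nRegions = 1L,
              smoothedField = numeric(nv), singleSign = TRUE)
  suppressWarnings(tab <- curvatureComparison(ssm, fitRSSM(meshes, lab1),
                                              modes = 1))
  ref <- curvatureSummary(meanMesh(ssm))
  expect_equal(tab$meanK[tab$scope == "whole"],
               rep(ref$meanK, 4), tolerance = 1e-12)
})

test_that("a pure scaling mode obeys the 1/s^2 curvature law", {
  set.seed(44)
  base <- icosphereMesh(2, 10)
  d <- as.vector(t(vertices(base)))  # scaling displacement field
  cohort <- linearCohort(base, matrix(d / sqrt(sum(d^2)), ncol = 1),
                         matrix(rnorm(100, sd = 0.6), ncol = 1))
  ssm <- fitSSM(cohort)
  up <- sdModel(ssm, 1, 2)
  dn <- sdModel(ssm, 1, -2)
  # the synthesized shapes are exact scaled copies of the sphere
  sUp <- max(vertices(up)[, 1]) / max(vertices(meanMesh(ssm))[, 1])
  sDn <- max(vertices(dn)[, 1]) / max(vertices(meanMesh(ssm))[, 1])
  kM <- curvatureSummary(meanMesh(ssm))$meanK
  expect_equal(curvatureSummary(up)$meanK, kM / sUp^2, tolerance = 1e-6)
  expect_equal(curvatureSummary(dn)$meanK, kM / sDn^2, tolerance = 1e-6)
})

test_that("the full pipeline is deterministic and reproducible", {
  cfg <- populationConfig(nSubjects = 6, templateResolution = c(12, 10),
                          seed = 777)
  r1 <- runPipeline(cfg, verbose = FALSE)
  r2 <- runPipeline(cfg, verbose = FALSE)
  expect_identical(r1@cumulativeVariance, r2@cumulativeVariance)
  expect_identical(r1@curvatureTable, r2@curvatureTable)
  expect_identical(r1@distanceTable, r2@distanceTable)
  expect_identical(r1@templateIndex, r2@templateIndex)
  expect_true(all(diff(r1@cumulativeVariance$nrSSM) >= -1e-12))
  expect_true(all(diff(r1@cumulativeVariance$rSSM) >= -1e-12))
})

test_that("pipeline artifacts land on disk and reload", {
  cfg <- populationConfig(nSubjects = 5, templateResolution = c(12, 10),
                          seed = 778)
  dir <- withr::local_tempdir()
  rep <- runPipeline(cfg, outDir = dir, verbose = FALSE)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "nrSSM_mean.ply")))
  expect_true(file.exists(file.path(dir, "log.txt")))
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_equal(as.numeric(js$cumulativeVariance$nrSSM),
               rep@cumulativeVariance$nrSSM, tolerance = 1e-12)
  tab <- read.csv(file.path(dir, "cumulative_variance.csv"))
  expect_equal(tab$rSSM, rep@cumulativeVariance$rSSM, tolerance = 1e-9)
})

test_that("a degenerate zero-variance cohort flows through end to end", {
  cfg <- populationConfig(nSubjects = 3,
                          modeSds = c(size = 0, width = 0, torsion = 0,
                                      bending = 0),
                          vertexNoiseSd = 0, misalignRotationSd = 0,
                          misalignTranslationSd = 0,
                          templateResolution = c(12, 10), seed = 9)
  w <- capture_warnings(rep <- runPipeline(cfg, verbose = FALSE))
  expect_true(any(grepl("zero variance", w)))
  expect_lt(max(rep@distanceTable$max), 1e-5)
  expect_lt(rep@templateRMS, 1e-6)
})

test_that("pipeline configs load from YAML with sections", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synthetic:",
               "  nSubjects: 5",
               "  templateResolution: [12, 10]",
               "  seed: 313",
               "report:",
               "  modes: 2"), p)
  rep <- runPipeline(p, verbose = FALSE)
  expect_equal(max(rep@curvatureTable$mode), 2)
  expect_error(readPipelineConfig(withr::local_tempfile(fileext = ".yaml",
                                                        lines = "a: 1")),
               "synthetic")
})
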