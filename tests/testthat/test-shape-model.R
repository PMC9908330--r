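test_that("a cohort of identical meshes gives a zero-variance model", {
  tm <- buildTemplate(c(10, 8))
  ssm <- fitSSM(list(tm, tm, tm))
  expect_true(all(modeVariances(ssm) < 1e-18))
  expect_equal(meanShape(ssm), as.vector(t(vertices(tm))),
               tolerance = 1e-12)
})

test_that("a single known generator mode is recovered exactly", {
  set.seed(21)
  base <- icosphereMesh(2, 10)
  p <- 3 * nVertices(base)
  d <- rnorm(p)
  d <- d / sqrt(sum(d^2))
  sigma <- 0.7
  w <- matrix(rnorm(500, sd = sigma), ncol = 1)
  cohort <- linearCohort(base, matrix(d, ncol = 1), w)
  ssm <- fitSSM(cohort)
  cosang <- abs(sum(shapeModes(ssm)[, 1] * d))
  expect_gt(cosang, 0.999)
  expect_lt(abs(modeVariances(ssm)[1] - sigma^2) / sigma^2, 0.15)

  # brute-force covariance eigendecomposition oracle
  X <- t(vapply(cohort, function(m) as.vector(t(vertices(m))), numeric(p)))
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(modeVariances(ssm)[1], ev$values[1], tolerance = 1e-10)
  expect_gt(abs(sum(shapeModes(ssm)[, 1] * ev$vectors[, 1])), 1 - 1e-10)

  # the +2SD shape displaces parallel to the generator direction
  plus <- sdModel(ssm, 1, 2)
  disp <- as.vector(t(vertices(plus))) - meanShape(ssm)
  expect_gt(abs(sum(disp * d)) / sqrt(sum(disp^2)), 0.999)
  expect_lt(abs(sqrt(sum(disp^2)) - 2 * sigma) / (2 * sigma), 0.15)
})

test_that("the n - 1 mode limit is enforced", {
  cfg <- populationConfig(nSubjects = 5, templateResolution = c(8, 8),
                          seed = 3)
  meshes <- samplePopulation(cfg)@meshes
  ssm <- fitSSM(meshes)
  expect_equal(nModes(ssm), 4L)
  expect_error(fitSSM(meshes, nModes = 5), "nTrain - 1")
  expect_silent(ssm4 <- fitSSM(meshes, nModes = 4))
  # 31 training shapes allow at most 30 modes
  pop31 <- samplePopulation(populationConfig(templateResolution = c(8, 8)))
  expect_equal(nModes(fitSSM(pop31@meshes)), 30L)
})

test_that("modes are orthonormal, sorted, and conserve variance", {
  cfg <- populationConfig(nSubjects = 12, seed = 5,
                          misalignRotationSd = 0, misalignTranslationSd = 0)
  meshes <- samplePopulation(cfg)@meshes
  ssm <- fitSSM(meshes)
  G <- crossprod(shapeModes(ssm))
  expect_lt(max(abs(G - diag(nModes(ssm)))), 1e-9)
  expect_true(all(diff(modeVariances(ssm)) <= 0))
  X <- t(vapply(meshes, function(m) as.vector(t(vertices(m))),
                numeric(3 * nVertices(meshes[[1]]))))
  total <- sum(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1)
  expect_lt(abs(sum(modeVariances(ssm)) - total) / total, 1e-9)
})

test_that("synthesis and projection are mutually inverse", {
  cfg <- populationConfig(nSubjects = 9, seed = 6,
                          misalignRotationSd = 0, misalignTranslationSd = 0)
  meshes <- samplePopulation(cfg)@meshes
  ssm <- fitSSM(meshes)

  expect_equal(vertices(synthesizeShape(ssm, numeric())),
               matrix(meanShape(ssm), ncol = 3, byrow = TRUE),
               tolerance = 0)
  expect_error(synthesizeShape(ssm, c(1, NaN)), "finite")
  expect_error(synthesizeShape(ssm, rnorm(nModes(ssm) + 1)), "weights")

  w0 <- rnorm(nModes(ssm))
  expect_equal(projectShape(ssm, synthesizeShape(ssm, w0)), w0,
               tolerance = 1e-10)
  expect_equal(projectShape(ssm, meanMesh(ssm)), rep(0, nModes(ssm)),
               tolerance = 1e-10)

  # full-mode reconstruction of every training mesh
  for (m in meshes) {
    rec <- synthesizeShape(ssm, projectShape(ssm, m))
    expect_lt(sqrt(mean((vertices(rec) - vertices(m))^2)), 1e-8)
  }
})

test_that("+/-2SD shapes are mirror images about the mean", {
  cfg <- populationConfig(nSubjects = 7, seed = 8)
  ssm <- fitSSM(samplePopulation(cfg)@meshes)
  up <- sdModel(ssm, 1, 2)
  dn <- sdModel(ssm, 1, -2)
  expect_equal((vertices(up) + vertices(dn)) / 2,
               matrix(meanShape(ssm), ncol = 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(vertices(sdModel(ssm, 1, 0)),
               matrix(meanShape(ssm), ncol = 3, byrow = TRUE),
               tolerance = 0)
  expect_equal(vertices(synthesizeShape(ssm, c(2 * sqrt(modeVariances(ssm)[1])))),
               vertices(up), tolerance = 0)
  expect_error(sdModel(ssm, nModes(ssm) + 1, 2), "out of range")
})

test_that("zero-variance modes synthesize the mean with a warning", {
  tm <- buildTemplate(c(10, 8))
  ssm <- fitSSM(list(tm, tm, tm))
  expect_warning(m <- sdModel(ssm, 1, 2), "zero variance")
  expect_equal(vertices(m), matrix(meanShape(ssm), ncol = 3, byrow = TRUE),
               tolerance = 0)
})

test_that("regional models with one region reduce to the global model", {
  cfg <- populationConfig(nSubjects = 8, seed = 10,
                          misalignRotationSd = 0, misalignTranslationSd = 0)
  meshes <- samplePopulation(cfg)@meshes
  nv <- nVertices(meshes[[1]])
  lab1 <- new("RegionLabeling", labels = rep(1L, nv), nRegions = 1L,
              smoothedField = numeric(nv), singleSign = TRUE)
  rssm1 <- fitRSSM(meshes, lab1)
  ssm <- fitSSM(meshes)
  expect_equal(modeVariances(rssm1@models[[1]]), modeVariances(ssm),
               tolerance = 1e-12)
  expect_equal(shapeModes(rssm1@models[[1]]), shapeModes(ssm),
               tolerance = 1e-12)
  expect_equal(vertices(sdModel(rssm1, 1, 2)), vertices(sdModel(ssm, 1, 2)),
               tolerance = 1e-12)
})

test_that("variation confined to one region stays out of the other", {
  set.seed(11)
  tm <- buildTemplate()
  lab <- partitionRegions(gaussianCurvature(tm), tm)
  nv <- nVertices(tm)
  idx2 <- which(regionLabels(lab) == 2L)
  cols2 <- as.vector(t(cbind(3 * idx2 - 2, 3 * idx2 - 1, 3 * idx2)))
  K <- 4
  D <- matrix(0, 3 * nv, K)
  D[cols2, ] <- rnorm(length(cols2) * K)
  D <- qr.Q(qr(D))[, 1:K]
  W <- matrix(rnorm(30 * K, sd = c(1, 0.6, 0.4, 0.2)), 30, K, byrow = TRUE)
  cohort <- linearCohort(tm, D, W)
  rmod <- fitRSSM(cohort, lab)
  expect_true(all(modeVariances(rmod@models[[1]]) <
                    1e-6 * rmod@models[[2]]@totalVariance))

  # per-region variance bookkeeping against direct computation
  X <- t(vapply(cohort, function(m) as.vector(t(vertices(m))),
                numeric(3 * nv)))
  for (r in 1:2) {
    idx <- which(regionLabels(lab) == r)
    cols <- as.vector(t(cbind(3 * idx - 2, 3 * idx - 1, 3 * idx)))
    tot <- sum(sweep(X[, cols], 2, colMeans(X[, cols]))^2) / (nrow(X) - 1)
    expect_equal(rmod@models[[r]]@totalVariance, tot, tolerance = 1e-9)
    expect_equal(sum(modeVariances(rmod@models[[r]])), tot,
                 tolerance = 1e-9)
  }
})

test_that("cumulative variance reaches 1 and tracks a known budget", {
  cfg <- populationConfig(nSubjects = 10, seed = 13)
  ssm <- fitSSM(samplePopulation(cfg)@meshes)
  cv <- cumulativeVariance(ssm)
  expect_equal(cv$cumulative[nrow(cv)], 1, tolerance = 1e-12)
  expect_true(all(diff(cv$cumulative) >= 0))

  # 6 modes carrying 85% of total variance against 15% isotropic noise
  set.seed(14)
  base <- icosphereMesh(2, 10)
  p <- 3 * nVertices(base)
  D <- qr.Q(qr(matrix(rnorm(p * 6), p, 6)))
  modeVar <- c(3, 2.5, 2, 1.5, 1, 0.5)
  modeVar <- modeVar * 0.85 / sum(modeVar)          # mode budget: 0.85
  noiseVar <- 0.15 / p                               # noise budget: 0.15
  W <- sapply(sqrt(modeVar), function(s) rnorm(500, sd = s))
  cohort <- linearCohort(base, D, W, noiseSd = sqrt(noiseVar))
  cv6 <- cumulativeVariance(fitSSM(cohort))
  expect_lt(abs(cv6$cumulative[6] - 0.85), 0.02)
})

test_that("shape models persist and reload faithfully", {
  cfg <- populationConfig(nSubjects = 6, templateResolution = c(8, 8),
                          seed = 15)
  ssm <- fitSSM(samplePopulation(cfg)@meshes)
  dir <- withr::local_tempdir()
  writeShapeModel(ssm, dir)
  back <- readShapeModel(dir)
  expect_equal(meanShape(back), meanShape(ssm), tolerance = 1e-12)
  expect_equal(shapeModes(back), shapeModes(ssm), tolerance = 1e-12)
  expect_equal(modeVariances(back), modeVariances(ssm), tolerance = 1e-12)
  expect_identical(back@faces, ssm@faces)
})
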