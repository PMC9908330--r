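test_that("cpdRigid self-registration returns the identity", {
  set.seed(1)
  P <- matrix(rnorm(300), 100, 3) %*% diag(c(10, 5, 2))
  reg <- cpdRigid(P, P)
  expect_lt(max(abs(rotation(reg$transform) - diag(3))), 1e-6)
  expect_lt(max(abs(translation(reg$transform))), 1e-6)
  expect_true(reg$converged)
})

test_that("cpdRigid recovers a known rigid transform", {
  set.seed(2)
  P <- matrix(rnorm(1500), 500, 3) %*% diag(c(15, 8, 4))
  R <- rotationAxisAngle(c(0, 0, 1), 30)
  tr <- c(1, 2, 3)
  Q <- sweep(P %*% t(R), 2, tr, "+")
  reg <- cpdRigid(P, Q)
  expect_lt(max(abs(rotation(reg$transform) - R)), 1e-4)
  expect_lt(max(abs(translation(reg$transform) - tr)), 1e-4)

  # with noise: sub-degree, sub-0.1 mm recovery
  Qn <- Q + matrix(rnorm(1500, sd = 0.1), 500, 3)
  regn <- cpdRigid(P, Qn)
  expect_lt(relRotationDeg(rotation(regn$transform), R), 0.5)
  expect_lt(sqrt(sum((translation(regn$transform) - tr)^2)), 0.1)
})

test_that("cpdRigid is equivariant under a common rigid transform", {
  set.seed(3)
  P <- matrix(rnorm(900), 300, 3) %*% diag(c(12, 6, 3))
  R <- rotationAxisAngle(c(1, 2, 0), 20)
  tr <- c(-2, 4, 1)
  Q <- sweep(P %*% t(R), 2, tr, "+")
  base <- cpdRigid(P, Q)$transform
  for (i in 1:3) {
    G <- rigidTransform(randomRotationMat(40), rnorm(3, sd = 5))
    regG <- cpdRigid(applyTransform(G, P), applyTransform(G, Q))$transform
    conj <- composeTransforms(composeTransforms(G, base), invertTransform(G))
    expect_lt(max(abs(rotation(regG) - rotation(conj))), 1e-5)
    expect_lt(max(abs(translation(regG) - translation(conj))), 1e-4)
  }
})

test_that("cpdRigid rejects degenerate input and flags non-convergence", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  good <- matrix(rnorm(30), 10, 3)
  expect_error(cpdRigid(line, good), "collinear")
  expect_error(cpdRigid(good[1:2, ], good), "at least 3")

  set.seed(4)
  P <- matrix(rnorm(600), 200, 3) %*% diag(c(10, 5, 2))
  Q <- applyTransform(rigidTransform(randomRotationMat(30), c(5, 0, 0)), P)
  reg <- cpdRigid(P, Q, maxIter = 2)
  expect_false(reg$converged)  # flag, not an exception
  expect_equal(reg$iterations, 2)
})

test_that("selectTemplate picks the centroid-most mesh deterministically", {
  tm <- buildTemplate(c(10, 8))
  same <- list(tm, tm, tm)
  sel <- selectTemplate(same)
  expect_equal(sel$templateIndex, 1L)  # tie broken by lowest index
  expect_lt(max(sel$rmsTable), 1e-6)

  # B is the exact midpoint of A and C along one deformation mode
  A <- applyModes(tm, c(width = -0.15))
  B <- tm
  C <- applyModes(tm, c(width = 0.15))
  sel2 <- selectTemplate(list(A, B, C))
  expect_equal(sel2$templateIndex, 2L)
  # brute-force property: selected mean RMS is the minimum
  expect_true(all(sel2$meanRMS[2] <= sel2$meanRMS + 1e-12))
  expect_equal(sel2$templateRMS, sel2$meanRMS[2])
})

test_that("establishCorrespondence projects template vertices onto the target", {
  tm <- buildTemplate(c(12, 10))
  # target = template: every vertex projects to itself
  out <- establishCorrespondence(tm, tm)
  expect_equal(vertices(out), vertices(tm), tolerance = 1e-6)
  expect_identical(faces(out), faces(tm))

  # pure translation: recovered geometry matches the target copy
  tr <- rigidTransform(diag(3), c(5, 0, 0))
  shifted <- applyTransform(tr, tm)
  out2 <- establishCorrespondence(tm, shifted)
  expect_lt(sqrt(mean(rowSums((vertices(out2) -
                                 vertices(shifted))^2))), 1e-4)

  # scaled target: projection lands on the target surface
  sc <- triangleMesh(1.1 * vertices(tm), faces(tm), name = "scaled")
  out3 <- establishCorrespondence(tm, sc)
  d <- rssm:::cpp_closest_on_mesh(vertices(out3), vertices(sc),
                                  faces(sc))$dist
  edge <- median(sqrt(rowSums((vertices(sc)[faces(sc)[, 1], ] -
                                 vertices(sc)[faces(sc)[, 2], ])^2)))
  expect_lt(sqrt(mean(d^2)), edge)
  expect_lt(max(d), 1e-8)  # projected points lie exactly on the surface
})

test_that("closest-point projection matches a brute-force oracle", {
  set.seed(8)
  tm <- icosphereMesh(1, 3)
  P <- matrix(rnorm(60, sd = 4), 20, 3)
  got <- rssm:::cpp_closest_on_mesh(P, vertices(tm), faces(tm))
  # brute force in R over every face
  for (i in 1:5) {
    best <- Inf
    for (f in seq_len(nFaces(tm))) {
      tri <- vertices(tm)[faces(tm)[f, ], ]
      # dense barycentric grid as an independent approximation
      g <- expand.grid(u = seq(0, 1, length.out = 60),
                       v = seq(0, 1, length.out = 60))
      g <- g[g$u + g$v <= 1, ]
      pts <- as.matrix(g) %*% tri[2:3, ] +
        outer(1 - g$u - g$v, tri[1, ])
      best <- min(best, min(sqrt(rowSums(sweep(pts, 2, P[i, ])^2))))
    }
    expect_equal(got$dist[i], best, tolerance = 1e-3)
    expect_lte(got$dist[i], best + 1e-12)  # exact projection can't be worse
  }
})

test_that("generalized Procrustes collapses rigid differences", {
  tm <- buildTemplate(c(10, 8))
  moved <- applyTransform(rigidTransform(randomRotationMat(25), c(3, -2, 1)),
                          tm)
  gpa <- generalizedProcrustes(list(tm, moved))
  expect_lt(sqrt(mean((vertices(gpa$meshes[[1]]) -
                         vertices(gpa$meshes[[2]]))^2)), 1e-6)
  expect_true(gpa$converged)
  expect_error(generalizedProcrustes(list(tm)), "at least 2")
})

test_that("an aligned, mean-centred cohort is a GPA fixed point", {
  set.seed(9)
  tm <- buildTemplate(c(10, 8))
  meshes <- lapply(1:4, function(i)
    triangleMesh(vertices(tm) + matrix(rnorm(nVertices(tm) * 3, sd = 0.01),
                                       ncol = 3),
                 faces(tm), name = paste0("m", i), validate = FALSE))
  pre <- generalizedProcrustes(meshes)
  post <- generalizedProcrustes(pre$meshes)
  for (s in seq_along(meshes))
    expect_equal(vertices(post$meshes[[s]]), vertices(pre$meshes[[s]]),
                 tolerance = 1e-8)
})

test_that("GPA objective is non-increasing and centroid size is preserved", {
  cfg <- populationConfig(nSubjects = 8, seed = 31)
  pop <- samplePopulation(cfg)
  gpa <- generalizedProcrustes(pop@meshes)
  expect_true(all(diff(gpa$objective) <= 1e-6 * gpa$objective[1]))
  csize <- function(V) sqrt(sum(sweep(V, 2, colMeans(V))^2))
  for (s in seq_along(pop@meshes))
    expect_equal(csize(vertices(gpa$meshes[[s]])),
                 csize(vertices(pop@meshes[[s]])), tolerance = 1e-9)
})

test_that("GPA recovers known misalignments up to a common pose", {
  cfg <- populationConfig(nSubjects = 8,
                          modeSds = c(size = 0, width = 0, torsion = 0,
                                      bending = 0),
                          vertexNoiseSd = 0.05, seed = 7)
  pop <- samplePopulation(cfg)
  gpa <- generalizedProcrustes(pop@meshes)
  comp <- mapply(composeTransforms, gpa$transforms, pop@trueTransforms,
                 SIMPLIFY = FALSE)
  rel <- vapply(comp[-1], function(x)
    rotationAngle(composeTransforms(x, invertTransform(comp[[1]]))), 0)
  expect_lt(max(rel), 1)
})
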