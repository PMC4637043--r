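test_that("load models match the published body-weight scalings", {
  expect_equal(stanceForce(700), 1750, tolerance = 1e-12)
  expect_equal(stanceForce(1), 2.5, tolerance = 1e-12)
  expect_equal(stanceForce(2 * 613), 2 * stanceForce(613), tolerance = 1e-12)
  expect_equal(impactForce(1, 170), 8.25, tolerance = 1e-12)
  expect_equal(impactForce(600, 170), 4950, tolerance = 1e-12)
  expect_equal(impactForce(600, 4 * 170), 2 * impactForce(600, 170),
               tolerance = 1e-12)
  expect_error(stanceForce(0), "positive")
  expect_error(impactForce(600, -1), "positive")
})

test_that("load cases balance forces and keep fixed and loaded sets disjoint", {
  mesh <- stdMesh()
  axes <- stdAxes()
  lcS <- buildLoadCase(mesh, "stance", w = 700, axes = axes)
  fsum <- colSums(lcS@nodeForces)
  expect_equal(sqrt(sum(fsum^2)), 1750, tolerance = 1e-9)
  expect_equal(as.vector(fsum / 1750), as.vector(-axes@shaftDir),
               tolerance = 1e-9)

  lcF <- buildLoadCase(mesh, "fall", w = 600, h = 170, axes = axes)
  fsum <- colSums(lcF@nodeForces)
  expect_equal(sqrt(sum(fsum^2)), 4950, tolerance = 1e-9)
  expect_lt(abs(sum(lcF@direction * axes@shaftDir)), 1e-9)

  for (lc in list(lcS, lcF)) {
    fixedNodes <- unique((lc@fixedDofs - 1L) %/% 3L + 1L)
    expect_length(intersect(fixedNodes, lc@loadedNodes), 0L)
  }
  expect_error(buildLoadCase(mesh, "fall", w = 700), "height")
})

test_that("axial bar solve reproduces the closed-form solution", {
  bar <- barWithE(1000)                      # L = 100, A = 100 mm^2
  mat <- binMaterials(bar)
  lc <- endLoadCase(bar, 1000)
  sol <- solveFE(bar, mat, lc)
  delta <- 1000 * 100 / (1000 * 100)         # FL/(EA) = 1 mm
  tip <- mean(displacements(sol)[lc@loadedNodes, 3])
  expect_lt(abs(tip - delta) / delta, 0.02)
  expect_lt(abs(totalStrainEnergy(sol) - 500) / 500, 0.02)
  # Clapeyron holds to solver precision
  expect_lt(abs(totalStrainEnergy(sol) - externalWork(sol)) /
            totalStrainEnergy(sol), 1e-6)
  # uniform uniaxial state: von Mises stress = F/A everywhere
  expect_lt(abs(max(vonMisesStress(sol)) - 10) / 10, 0.05)
  expect_equal(unname(stats::sd(vonMisesStress(sol))), 0, tolerance = 1e-6)
})

test_that("zero load produces zero displacements and energy", {
  bar <- barWithE(1000, length = 50, side = 10, edge = 5)
  mat <- binMaterials(bar)
  lc <- endLoadCase(bar, 1000)
  lc@nodeForces <- lc@nodeForces * 0
  lc@totalForce <- 0
  sol <- solveFE(bar, mat, lc)
  expect_equal(max(abs(displacements(sol))), 0, tolerance = 1e-12)
  expect_equal(totalStrainEnergy(sol), 0, tolerance = 1e-12)
})

test_that("solution scales linearly in force and quadratically in energy", {
  bar <- barWithE(2000, length = 50, side = 10, edge = 5)
  mat <- binMaterials(bar)
  lc1 <- endLoadCase(bar, 500)
  lc2 <- endLoadCase(bar, 1000)
  s1 <- solveFE(bar, mat, lc1)
  s2 <- solveFE(bar, mat, lc2)
  expect_equal(displacements(s2), 2 * displacements(s1), tolerance = 1e-9)
  expect_equal(totalStrainEnergy(s2), 4 * totalStrainEnergy(s1),
               tolerance = 1e-9)
})

test_that("reciprocity (Betti) holds between two load cases on the same body", {
  # d1 . f2 == d2 . f1 requires a symmetric stiffness operator
  bar <- barWithE(1500, length = 60, side = 12, edge = 6)
  mat <- binMaterials(bar)
  lcA <- endLoadCase(bar, 800)
  lcB <- endLoadCase(bar, 800)
  # second case: bend the bar with a transverse force at the free end
  lcB@nodeForces <- lcB@nodeForces[, c(3, 2, 1)]
  lcB@direction <- lcB@direction[c(3, 2, 1)]
  sA <- solveFE(bar, mat, lcA)
  sB <- solveFE(bar, mat, lcB)
  fvec <- function(lc, n) {
    f <- matrix(0, n, 3)
    f[lc@loadedNodes, ] <- lc@nodeForces
    f
  }
  n <- nNodes(bar)
  w12 <- sum(displacements(sA) * fvec(lcB, n))
  w21 <- sum(displacements(sB) * fvec(lcA, n))
  expect_equal(w12, w21, tolerance = 1e-9 * abs(w12))
})

test_that("rigid-body displacement fields carry no strain", {
  set.seed(3)
  tested <- 0
  while (tested < 10) {
    p <- matrix(rnorm(12), 4, 3)
    # skip slivers: their gradient matrices amplify round-off arbitrarily
    if (abs(det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ]))) < 0.1)
      next
    tested <- tested + 1
    bv <- femfri:::.tetBMatrix(p)
    trans <- rep(rnorm(3), 4)                        # uniform translation
    expect_equal(max(abs(bv$B %*% trans)), 0, tolerance = 1e-12)
    w <- rnorm(3)                                    # linearized rotation
    # apply() returns one 3-vector per node as columns; flatten column-major
    # to get the (u1, v1, w1, u2, ...) DOF ordering
    rot <- as.vector(apply(p, 1, function(x) c(w[2] * x[3] - w[3] * x[2],
                                               w[3] * x[1] - w[1] * x[3],
                                               w[1] * x[2] - w[2] * x[1])))
    expect_lt(max(abs(bv$B %*% rot)), 1e-8 * max(abs(w)))
  }
})

test_that("von Mises fields follow the closed forms for canonical states", {
  # hydrostatic stress: zero deviator
  s <- matrix(c(5, 5, 5, 0, 0, 0), 1, 6)
  expect_equal(femfri:::.vonMisesStressVoigt(s)[1], 0, tolerance = 1e-12)
  # uniaxial stress sigma -> von Mises = |sigma|
  s <- matrix(c(-7, 0, 0, 0, 0, 0), 1, 6)
  expect_equal(femfri:::.vonMisesStressVoigt(s)[1], 7, tolerance = 1e-12)
  # uniaxial strain state (eps, -nu eps, -nu eps): equivalent strain = eps
  nu <- 0.4; eps <- 2e-3
  e <- matrix(c(eps, -nu * eps, -nu * eps, 0, 0, 0), 1, 6)
  expect_equal(femfri:::.vonMisesStrainVoigt(e, nu)[1], eps,
               tolerance = 1e-12)
})

test_that("under-constrained systems fail with a diagnostic", {
  bar <- barWithE(1000, length = 50, side = 10, edge = 5)
  mat <- binMaterials(bar)
  lc <- endLoadCase(bar, 1000)
  lc@fixedDofs <- lc@fixedDofs[1:2]            # rigid-body modes remain
  expect_error(solveFE(bar, mat, lc),
               "positive definite|singular|rigid-body")
})
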