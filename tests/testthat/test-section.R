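test_that("quadrature rules integrate polynomials to their design degree", {
  r3 <- gaussRule(3)
  r7 <- gaussRule(7)
  expect_equal(sum(r3@weights), 0.5, tolerance = 1e-15)
  expect_equal(sum(r7@weights), 0.5, tolerance = 1e-15)

  # all monomials x^a y^b up to total degree 2 (3-point) / 5 (7-point),
  # against the closed-form reference-triangle integral a! b!/(a + b + 2)!
  for (a in 0:2) for (b in 0:(2 - a)) {
    expect_equal(applyRuleRef(r3, function(x, y) x^a * y^b),
                 refTriMonomial(a, b), tolerance = 1e-14,
                 label = sprintf("3-point x^%d y^%d", a, b))
  }
  for (a in 0:5) for (b in 0:(5 - a)) {
    expect_equal(applyRuleRef(r7, function(x, y) x^a * y^b),
                 refTriMonomial(a, b), tolerance = 1e-13,
                 label = sprintf("7-point x^%d y^%d", a, b))
  }
  # random degree-5 polynomial, 1e-12 relative
  set.seed(5)
  cf <- rnorm(21)
  k <- 0
  f <- function(x, y) {
    out <- 0; k <- 0
    for (a in 0:5) for (b in 0:(5 - a)) { k <- k + 1; out <- out + cf[k] * x^a * y^b }
    out
  }
  exact <- { k <- 0; s <- 0
    for (a in 0:5) for (b in 0:(5 - a)) { k <- k + 1; s <- s + cf[k] * refTriMonomial(a, b) }
    s }
  expect_equal(applyRuleRef(r7, f), exact, tolerance = 1e-12)
  # 3-point rule is NOT exact at degree 3 (sanity of the degree claim)
  expect_gt(abs(applyRuleRef(r3, function(x, y) x^3) - refTriMonomial(3, 0)),
            1e-6)
  expect_error(gaussRule(4), "unsupported")
})

test_that("section triangulation tiles the slice exactly and refines", {
  cyl <- generateCylinderFixture(10, 50, 2, 500)
  pl <- sectionPlane(c(0, 0, 25), c(0, 0, 1))
  tri5 <- triangulateSection(cyl, pl, maxEdge = 5)
  A <- sum(femfri:::.triAreas(tri5@vertices, tri5@triangles))
  expect_lt(abs(A - pi * 100) / (pi * 100), 0.02)
  expect_equal(A, tri5@plane@area, tolerance = 1e-9)

  tri25 <- triangulateSection(cyl, pl, maxEdge = 2.5)
  expect_gt(nrow(tri25@triangles), nrow(tri5@triangles))
  edges <- function(tr) {
    e <- rbind(tr@triangles[, 1:2], tr@triangles[, 2:3], tr@triangles[, c(3, 1)])
    max(sqrt(rowSums((tr@vertices[e[, 1], ] - tr@vertices[e[, 2], ])^2)))
  }
  expect_lte(edges(tri5), 5)
  expect_lte(edges(tri25), 2.5)

  # tet-aligned mode: every triangle centroid lies in its recorded tet
  triT <- triangulateSection(cyl, pl, maxEdge = 5, align = "tets")
  ctr2 <- (triT@vertices[triT@triangles[, 1], ] +
           triT@vertices[triT@triangles[, 2], ] +
           triT@vertices[triT@triangles[, 3], ]) / 3
  ctr3 <- sweep(ctr2 %*% t(triT@basis), 2, triT@plane@origin, `+`)
  nd <- nodes(cyl); el <- elements(cyl)
  for (i in seq_len(nrow(ctr3))) {
    en <- el[triT@triTet[i], ]
    M <- rbind(nd[en[2], ] - nd[en[1], ], nd[en[3], ] - nd[en[1], ],
               nd[en[4], ] - nd[en[1], ])
    bb <- as.vector((ctr3[i, ] - nd[en[1], ]) %*% solve(M))
    expect_gte(min(1 - sum(bb), bb), -1e-9)
  }
  expect_error(triangulateSection(cyl, sectionPlane(c(0, 0, 80), c(0, 0, 1))),
               "does not intersect")
})

test_that("uniform fields integrate exactly and match closed forms", {
  # homogeneous bar under uniaxial stress: U = u0 * A, U_Y = A sigmaY^2/(2E),
  # eta = (sigma / sigma_Y)^2
  rho1hu <- (1 - 0.04162) / 0.000854        # ash density exactly 1 g/cm^3
  bar <- generateBarFixture(100, 10, 5, rho1hu)
  mat <- binMaterials(bar)
  expect_equal(materialBins(mat)$E, 10500, tolerance = 1e-9)
  expect_equal(materialBins(mat)$sigma_Y, 116, tolerance = 1e-9)
  lc <- endLoadCase(bar, 1000)              # sigma = 10 MPa uniform
  sol <- solveFE(bar, mat, lc)
  pl <- sectionPlane(c(5, 5, 50), c(0, 0, 1))
  tri <- triangulateSection(bar, pl, maxEdge = 5)
  A <- tri@plane@area
  expect_equal(A, 100, tolerance = 1e-9)

  u0 <- energyDensity(sol)[1]
  for (rule in list(gaussRule(3), gaussRule(7))) {
    U <- sectionStrainEnergy(sol, bar, tri, rule)
    UY <- sectionYieldEnergy(mat, bar, tri, rule)
    expect_equal(U, u0 * A, tolerance = 1e-9)
    expect_equal(UY, A * 116^2 / (2 * 10500), tolerance = 1e-9)
    expect_equal(fractureRiskIndex(U, UY), (10 / 116)^2, tolerance = 1e-9)
  }
  # hand value for the yield energy at unit density over 100 mm^2
  expect_lt(abs(sectionYieldEnergy(mat, bar, tri) - 64.076), 0.001)

  mx <- sectionFieldMaxima(sol, tri)
  expect_lt(abs(mx["stress"] - 10) / 10, 0.05)

  lc0 <- lc; lc0@nodeForces <- lc0@nodeForces * 0; lc0@totalForce <- 0
  sol0 <- solveFE(bar, mat, lc0)
  expect_equal(unname(sectionFieldMaxima(sol0, tri)), c(0, 0),
               tolerance = 1e-12)
  expect_error(fractureRiskIndex(1, 0), "positive")
})

test_that("quadrature equals the brute-force triangle sum for tet-aligned sections", {
  mesh <- stdMesh()
  mat <- stdMaterials()
  sol <- stdSolution("fall")
  tri <- stdTriangulation("smallest_neck", align = "tets")
  dens <- energyDensity(sol)
  brute <- sum(femfri:::.triAreas(tri@vertices, tri@triangles) *
               dens[tri@triTet])
  U3 <- sectionStrainEnergy(sol, mesh, tri, gaussRule(3))
  U7 <- sectionStrainEnergy(sol, mesh, tri, gaussRule(7))
  expect_equal(U3, brute, tolerance = 1e-12)
  expect_equal(U7, brute, tolerance = 1e-12)
})

test_that("section energy scales quadratically with the applied load", {
  bar <- barWithE(3000, length = 60, side = 12, edge = 6)
  mat <- binMaterials(bar)
  s1 <- solveFE(bar, mat, endLoadCase(bar, 400))
  s2 <- solveFE(bar, mat, endLoadCase(bar, 800))
  tri <- triangulateSection(bar, sectionPlane(c(6, 6, 30), c(0, 0, 1)),
                            maxEdge = 4)
  U1 <- sectionStrainEnergy(s1, bar, tri)
  U2 <- sectionStrainEnergy(s2, bar, tri)
  expect_equal(U2, 4 * U1, tolerance = 1e-9)
  UY <- sectionYieldEnergy(mat, bar, tri)
  expect_equal(fractureRiskIndex(U2, UY), 4 * fractureRiskIndex(U1, UY),
               tolerance = 1e-9)
})

test_that("yield energy is independent of the load case", {
  mesh <- stdMesh()
  mat <- stdMaterials()
  tri <- stdTriangulation("smallest_neck")
  UY <- sectionYieldEnergy(mat, mesh, tri)
  expect_gt(UY, 0)
  # same quantity computed after any solve is unchanged (material-only)
  expect_identical(UY, sectionYieldEnergy(mat, mesh, tri))
})
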