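test_that("phantom generation is seeded-deterministic and respects the edge bound", {
  spec <- phantomSpec(targetEdgeLength = 12, seed = 7L)
  m1 <- generatePhantom(spec)
  m2 <- generatePhantom(spec)
  expect_identical(nodes(m1), nodes(m2))
  expect_identical(elements(m1), elements(m2))
  expect_identical(elementHU(m1), elementHU(m2))

  el <- elements(m1); nd <- nodes(m1)
  edges <- rbind(el[, c(1, 2)], el[, c(1, 3)], el[, c(1, 4)],
                 el[, c(2, 3)], el[, c(2, 4)], el[, c(3, 4)])
  maxEdge <- max(sqrt(rowSums((nd[edges[, 1], ] - nd[edges[, 2], ])^2)))
  expect_lte(maxEdge, 12)
  expect_true(all(tetVolumes(m1) > 0))
})

test_that("phantom ground truth and noiseless HU fields are exact", {
  spec <- phantomSpec(neckShaftAngle = 130, huNoiseSD = 0,
                      targetEdgeLength = 12)
  mesh <- generatePhantom(spec)
  expect_identical(groundTruth(mesh)$neck_shaft_angle, 130)
  expect_true(all(elementHU(mesh) %in% c(1200, 150)))
  # both tissue classes must be present
  expect_true(all(c(1200, 150) %in% elementHU(mesh)))
  # noise changes interior values but not geometry
  noisy <- generatePhantom(phantomSpec(neckShaftAngle = 130,
                                       targetEdgeLength = 12))
  expect_identical(nodes(noisy), nodes(mesh))
  expect_false(identical(elementHU(noisy), elementHU(mesh)))
  expect_true(all(elementHU(noisy) >= 1))
})

test_that("phantom is a single connected component", {
  mesh <- generatePhantom(phantomSpec(targetEdgeLength = 12))
  el <- elements(mesh)
  n <- nNodes(mesh)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in seq_len(nrow(el))) {
    r <- find(el[e, 1])
    for (k in 2:4) { s <- find(el[e, k]); if (s != r) parent[s] <- r }
  }
  expect_length(unique(vapply(seq_len(n), find, integer(1))), 1L)
})

test_that("phantom volume matches a Monte Carlo estimate of the implicit solid", {
  spec <- phantomSpec()
  mesh <- generatePhantom(spec)
  geo <- femfri:::.femurGeometry(spec)
  set.seed(42)
  npt <- 2e5
  lo <- geo$bbox[1, ]; hi <- geo$bbox[2, ]
  P <- cbind(runif(npt, lo[1], hi[1]), runif(npt, lo[2], hi[2]),
             runif(npt, lo[3], hi[3]))
  frac <- mean(geo$F(P) < 0)
  vMC <- frac * prod(hi - lo)
  expect_lt(abs(sum(tetVolumes(mesh)) - vMC) / vMC, 0.02)
})

test_that("infeasible phantom geometry is rejected with a descriptive error", {
  expect_error(phantomSpec(corticalThickness = 16, neckRadius = 15),
               "corticalThickness")
  expect_error(generatePhantom(phantomSpec(corticalThickness = 12,
                                           shaftRadius = 10)),
               "infeasible")
  expect_error(phantomSpec(neckShaftAngle = 80), "90, 180")
  expect_error(phantomSpec(corticalHU = 100, cancellousHU = 150),
               "corticalHU")
})

test_that("bar fixture conserves volume exactly and geometry is HU-independent", {
  bar <- generateBarFixture(100, 10, 5, 1000)
  expect_equal(sum(tetVolumes(bar)), 100 * 10 * 10, tolerance = 1e-9)
  bar2 <- generateBarFixture(100, 10, 5, 500)
  expect_identical(nodes(bar), nodes(bar2))
  expect_identical(elements(bar), elements(bar2))
  expect_equal(unique(elementHU(bar2)), 500)
  expect_error(generateBarFixture(100, 10, 12, 1000), "edge length")
  expect_error(generateBarFixture(-1, 10, 5, 1000), "positive")
})

test_that("cylinder fixture reproduces analytic area and volume within faceting error", {
  cyl <- generateCylinderFixture(10, 50, 2, 500)
  expect_lt(abs(sum(tetVolumes(cyl)) - pi * 100 * 50) / (pi * 100 * 50),
            0.02)
  a <- crossSectionArea(cyl, c(0, 0, 25), c(0, 0, 1))
  expect_lt(abs(a - pi * 100) / (pi * 100), 0.02)
  # slicing outside the solid yields an empty section
  expect_warning(a0 <- crossSectionArea(cyl, c(0, 0, 60), c(0, 0, 1)),
                 "does not intersect")
  expect_identical(a0, 0)
})

test_that("VTK and CSV round trips preserve the mesh", {
  mesh <- generatePhantom(phantomSpec(targetEdgeLength = 14))
  tmp <- tempfile(fileext = ".vtk")
  writeMeshVTK(mesh, tmp)
  back <- readMeshVTK(tmp)
  expect_equal(nodes(back), nodes(mesh), tolerance = 1e-12)
  expect_identical(elements(back), elements(mesh))
  expect_equal(elementHU(back), elementHU(mesh), tolerance = 1e-12)
  expect_equal(landmarks(back)$head_centre, landmarks(mesh)$head_centre,
               tolerance = 1e-12)
  expect_equal(groundTruth(back)$neck_shaft_angle, 130)

  stem <- tempfile()
  writeMeshCSV(mesh, stem)
  back2 <- readMeshCSV(stem)
  expect_equal(nodes(back2), nodes(mesh), tolerance = 1e-12)
  expect_identical(elements(back2), elements(mesh))
  expect_equal(landmarks(back2)$lesser_trochanter,
               landmarks(mesh)$lesser_trochanter, tolerance = 1e-12)
})
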