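test_that("sphere fit is exact on noise-free data and robust to noise", {
  set.seed(11)
  dirs <- matrix(rnorm(60), 20, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(5 * dirs, 2, c(1, 2, 3), `+`)
  fit <- fitSphere(pts)
  expect_equal(fit$centre, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(fit$radius, 5, tolerance = 1e-9)

  # noisy fit: compare with direct nonlinear least squares
  set.seed(12)
  dirs <- matrix(rnorm(1500), 500, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  noisy <- sweep(5 * dirs, 2, c(1, 2, 3), `+`) +
    matrix(rnorm(1500, sd = 0.1), 500, 3)
  fitA <- fitSphere(noisy)
  obj <- function(p) {
    r <- sqrt(rowSums(sweep(noisy, 2, p[1:3])^2))
    sum((r - p[4])^2)
  }
  fitN <- stats::optim(c(fitA$centre, fitA$radius), obj,
                       method = "BFGS")$par
  expect_lt(sqrt(sum((fitA$centre - c(1, 2, 3))^2)), 0.05)
  expect_lt(sqrt(sum((fitA$centre - fitN[1:3])^2)), 0.02)

  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_error(fitSphere(square), "degenerate|coplanar")
  expect_error(fitSphere(pts[1:3, ]), "at least 4")
})

test_that("axis fit recovers cylinder axes and normalizes orientation", {
  grid <- expand.grid(th = seq(0, 2 * pi, length.out = 25)[-25],
                      z = seq(0, 40, length.out = 17))
  pts <- cbind(8 * cos(grid$th), 8 * sin(grid$th), grid$z)
  fit <- fitAxis(pts)
  expect_gt(abs(sum(fit$direction * c(0, 0, 1))), cos(1 * pi / 180))
  expect_gte(sum(fit$direction * c(0, 0, 1)), 0)   # proximal convention

  line <- outer(seq(0, 10, length.out = 9), c(1, 1, 1) / sqrt(3))
  fit <- fitAxis(line, orient = c(1, 1, 1))
  expect_equal(fit$direction, c(1, 1, 1) / sqrt(3), tolerance = 1e-9)

  expect_error(fitAxis(matrix(1, 5, 3)), "zero-spread")
  expect_error(fitAxis(line[1:2, ]), "at least 3")
})

test_that("sphere and axis fits are equivariant under rigid motions", {
  set.seed(31)
  dirs <- matrix(rnorm(90), 30, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sph <- sweep(3 * dirs, 2, c(2, -1, 4), `+`)
  th <- runif(200, 0, 2 * pi)
  cyl <- cbind(5 * cos(th), 5 * sin(th), runif(200, 0, 30))
  R <- rigidRotation(c(1, 2, 3), 0.7)
  tr <- c(10, -5, 2)
  mv <- function(P) sweep(P %*% t(R), 2, tr, `+`)

  f0 <- fitSphere(sph); f1 <- fitSphere(mv(sph))
  expect_equal(f1$centre, as.vector(R %*% f0$centre + tr), tolerance = 1e-9)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-9)

  a0 <- fitAxis(cyl)
  a1 <- fitAxis(mv(cyl), orient = as.vector(R %*% a0$direction))
  expect_equal(abs(sum(a1$direction * (R %*% a0$direction))), 1,
               tolerance = 1e-9)
})

test_that("neck-shaft angle recovery and boundary flagging", {
  mesh <- stdMesh()
  axes <- stdAxes()
  expect_lt(abs(axes@angle - 130), 2)

  ortho <- new("FemoralAxes", headCentre = c(0, 0, 0), headRadius = 1,
               neckDir = c(1, 0, 0), neckPoint = c(0, 0, 0),
               shaftDir = c(0, 0, 1), shaftPoint = c(0, 0, -10),
               angle = NA_real_)
  expect_warning(a <- neckShaftAngle(ortho), "outside the anatomical range")
  expect_equal(a, 90)
  anti <- ortho
  anti@neckDir <- c(0, 0, -1)
  expect_warning(a <- neckShaftAngle(anti), "outside the anatomical range")
  expect_equal(a, 180)
})

test_that("critical sections land on their defining features", {
  mesh <- stdMesh()
  axes <- stdAxes()
  secs <- stdSections()
  gt <- groundTruth(mesh)

  # subtrochanteric: exactly 50 mm distal of the lesser trochanter
  expect_equal(secs$subtrochanteric@origin,
               landmarks(mesh)$lesser_trochanter - 50 * axes@shaftDir,
               tolerance = 1e-12)

  # smallest neck: at the machined waist, within a couple of sampling steps
  dWaist <- sqrt(sum((secs$smallest_neck@origin - gt$waist_centre)^2))
  expect_lt(dWaist, 3)
  expect_gt(secs$intertrochanteric@area, secs$smallest_neck@area)

  # smallest-neck area is minimal across the sampled neck span
  tJ <- femfri:::.lineClosestApproach(axes@neckPoint, axes@neckDir,
                                      axes@shaftPoint, axes@shaftDir)
  for (t in seq(0.5 * tJ, 0.95 * tJ, by = 4)) {
    a <- crossSectionArea(mesh, axes@neckPoint + t * axes@neckDir,
                          axes@neckDir)
    expect_gte(a + 1e-9, secs$smallest_neck@area)
  }
})

test_that("a sharply machined waist is located within one sampling step", {
  spec <- phantomSpec(waistDepth = 4, waistWidth = 5, huNoiseSD = 0)
  mesh <- generatePhantom(spec)
  axes <- femoralAxes(mesh)
  secs <- findCriticalSections(mesh, axes, step = 1)
  gt <- groundTruth(mesh)
  along <- abs(sum((secs$smallest_neck@origin - gt$waist_centre) *
                   axes@neckDir))
  expect_lte(along, 1.5)   # one 1 mm step plus axis-estimation slack
})

test_that("cross-section areas are rotation invariant and geometrically exact", {
  cyl <- generateCylinderFixture(10, 50, 2, 500)
  a0 <- crossSectionArea(cyl, c(0, 0, 25), c(0, 0, 1))
  expect_lt(abs(a0 - pi * 100) / (pi * 100), 0.02)

  R <- rigidRotation(c(2, 1, 1), 1.1)
  rot <- tetMesh(nodes(cyl) %*% t(R), elements(cyl), elementHU(cyl))
  a1 <- crossSectionArea(rot, as.vector(R %*% c(0, 0, 25)),
                         as.vector(R %*% c(0, 0, 1)))
  expect_equal(a1, a0, tolerance = 1e-9)

  # plane tangent to the surface: near-zero area
  atan_ <- tryCatch(crossSectionArea(cyl, c(0, 9.999, 25), c(0, 1, 0)),
                    warning = function(w) 0)
  expect_lt(atan_, 8)
})
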