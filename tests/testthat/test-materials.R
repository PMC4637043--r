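test_that("HU to ash density calibration matches the published linear form", {
  expect_equal(ashDensityFromHU(0), 0.04162, tolerance = 1e-12)
  expect_equal(ashDensityFromHU(1000), 0.89562, tolerance = 1e-12)
  expect_equal(ashDensityFromHU(200), 0.21242, tolerance = 1e-12)
  # clamp protects the power laws from air-like voxels
  expect_equal(ashDensityFromHU(-500), 0.01)
  expect_error(ashDensityFromHU(NA), "finite")
  expect_error(ashDensityFromHU(Inf), "finite")
})

test_that("density power laws reproduce published values and are increasing", {
  expect_equal(youngModulus(1), 10500, tolerance = 1e-12)
  expect_equal(youngModulus(0.5), 10500 * 0.5^2.29, tolerance = 1e-12)
  expect_lt(abs(youngModulus(0.5) - 2146.993), 0.1)
  expect_equal(yieldStress(1), 116, tolerance = 1e-12)
  expect_lt(abs(yieldStress(0.5) - 28.40), 0.05)
  rho <- seq(0.05, 2, length.out = 50)
  expect_true(all(diff(youngModulus(rho)) > 0))
  expect_true(all(diff(yieldStress(rho)) > 0))
  expect_error(youngModulus(0), "positive")
  expect_error(yieldStress(-1), "positive")
})

test_that("binning partitions elements with representative mean densities", {
  # degenerate: identical HU collapses to one bin regardless of nBins
  mt <- binMaterials(rep(750, 20), nBins = 50)
  expect_identical(nrow(materialBins(mt)), 1L)
  expect_equal(materialBins(mt)$E, youngModulus(ashDensityFromHU(750)))

  # single requested bin: representative density is the element mean
  mt1 <- binMaterials(c(100, 400, 1000), nBins = 1)
  expect_identical(nrow(materialBins(mt1)), 1L)
  expect_equal(materialBins(mt1)$density,
               mean(ashDensityFromHU(c(100, 400, 1000))))

  # two spread elements, two bins: one element each, hand-computed densities
  mt2 <- binMaterials(c(100, 2000), nBins = 2)
  expect_identical(nrow(materialBins(mt2)), 2L)
  expect_equal(materialBins(mt2)$density, c(0.12702, 1.74962),
               tolerance = 1e-9)
  expect_identical(elementBins(mt2), c(1L, 2L))
  expect_error(binMaterials(numeric(0)), "empty")
})

test_that("binning preserves density ordering and refines to the exact values", {
  hu <- seq(100, 2000, by = 100)
  b <- materialBins(binMaterials(hu, nBins = 7))
  expect_true(!is.unsorted(b$density))
  expect_true(!is.unsorted(b$E))
  expect_true(!is.unsorted(b$sigma_Y))
  # equally spaced values, one bin per distinct value: binning becomes exact
  mt <- binMaterials(hu, nBins = length(hu))
  expect_equal(elementE(mt), youngModulus(ashDensityFromHU(hu)),
               tolerance = 1e-12)
  # yield energy density is positive and finite for every bin
  u <- yieldEnergyDensity(b$E, b$sigma_Y)
  expect_true(all(is.finite(u) & u > 0))
})

test_that("elasticity matrix matches the isotropic closed form", {
  D <- elasticityMatrix(1, 0.4)
  expect_equal(D[1, 1], 0.6 / 0.28, tolerance = 1e-12)
  expect_equal(D[1, 2], 0.4 / 0.28, tolerance = 1e-12)
  expect_equal(D[4, 4], 0.1 / 0.28, tolerance = 1e-12)
  expect_identical(D[1, 4], 0)
  for (E in c(1, 12000)) for (nu in c(0.25, 0.4, 0.49)) {
    D <- elasticityMatrix(E, nu)
    expect_equal(D, t(D))
    expect_true(all(eigen(D, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
  expect_equal(elasticityMatrix(2, 0.4), 2 * elasticityMatrix(1, 0.4))
  expect_error(elasticityMatrix(1, 0.5), "singular")
  expect_error(elasticityMatrix(-1, 0.4), "positive")
})
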