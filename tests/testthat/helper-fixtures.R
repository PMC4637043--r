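# Shared fixtures, built lazily once per test session.  The "standard run"
# is the default phantom (seed 1) with 50 material bins, solved under both
# configurations, with the three critical sections located.

.fixtures <- new.env(parent = emptyenv())

.memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

stdMesh <- function() .memo("mesh", function() generatePhantom(phantomSpec()))

stdMaterials <- function() .memo("materials", function()
  binMaterials(stdMesh(), nBins = 50))

stdAxes <- function() .memo("axes", function() femoralAxes(stdMesh()))

stdSections <- function() .memo("sections", function()
  findCriticalSections(stdMesh(), stdAxes()))

stdSolution <- function(configuration = c("fall", "stance")) {
  configuration <- match.arg(configuration)
  .memo(paste0("sol_", configuration), function() {
    lc <- buildLoadCase(stdMesh(), configuration, w = 700, h = 170,
                        axes = stdAxes())
    solveFE(stdMesh(), stdMaterials(), lc)
  })
}

stdTriangulation <- function(label = "smallest_neck",
                             align = c("boundary", "tets")) {
  align <- match.arg(align)
  .memo(paste0("tri_", label, "_", align), function()
    triangulateSection(stdMesh(), stdSections()[[label]], maxEdge = 5,
                       align = align))
}

# Uniform bar with a prescribed Young's modulus, via inversion of the
# HU -> density -> modulus chain.
barWithE <- function(E, length = 100, side = 10, edge = 5) {
  rho <- (E / 10500)^(1 / 2.29)
  hu <- (rho - 0.04162) / 0.000854
  generateBarFixture(length, side, edge, hu)
}

# Exact monomial integral over the reference triangle {(x, y): x, y >= 0,
# x + y <= 1}: a! b! / (a + b + 2)!  (independent closed-form oracle).
refTriMonomial <- function(a, b) {
  factorial(a) * factorial(b) / factorial(a + b + 2)
}

# Apply a quadrature rule to f on the reference triangle: with vertices
# (0,0), (1,0), (0,1) the Jacobian determinant is 1, so the integral is
# simply sum(W_i f(x_i)).
applyRuleRef <- function(rule, f) {
  x <- rule@bary %*% c(0, 1, 0)
  y <- rule@bary %*% c(0, 0, 1)
  sum(rule@weights * f(x, y))
}

rigidRotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c + s * K + (1 - c) * outer(a, a)
}
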