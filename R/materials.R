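#' HU to ash density calibration
#'
#' Linear calibration from Hounsfield units to bone ash density,
#' \eqn{\rho_{ash} = 0.04162 + 0.000854\,HU} (g/cm^3).  The result is clamped
#' below at \code{clamp} so that downstream power laws never see a
#' nonpositive density (relevant only for HU below about -37, i.e. air or
#' marrow voxels outside the usual bone segmentation window).
#'
#' @param hu numeric, Hounsfield units.
#' @param clamp lower density bound, g/cm^3.
#' @return ash density, g/cm^3.
#' @examples
#' ashDensityFromHU(c(0, 200, 1000))
#' @export
ashDensityFromHU <- function(hu, clamp = 0.01) {
  if (any(!is.finite(hu))) stop("hu must be finite")
  pmax(0.04162 + 0.000854 * hu, clamp)
}

#' Density to Young's modulus power law
#'
#' \eqn{E = 10500\,\rho_{ash}^{2.29}} (MPa).
#'
#' @param rhoAsh ash density, g/cm^3; must be positive.
#' @return Young's modulus, MPa.
#' @examples
#' youngModulus(1)     # 10500 MPa at unit ash density
#' @export
youngModulus <- function(rhoAsh) {
  if (any(!is.finite(rhoAsh)) || any(rhoAsh <= 0))
    stop("rhoAsh must be positive and finite")
  10500 * rhoAsh^2.29
}

#' Density to yield stress power law
#'
#' \eqn{\sigma_Y = 116\,\rho_{ash}^{2.03}} (MPa).
#'
#' @inheritParams youngModulus
#' @return yield stress, MPa.
#' @examples
#' yieldStress(1)      # 116 MPa at unit ash density
#' @export
yieldStress <- function(rhoAsh) {
  if (any(!is.finite(rhoAsh)) || any(rhoAsh <= 0))
    stop("rhoAsh must be positive and finite")
  116 * rhoAsh^2.03
}

#' Yield strain-energy density
#'
#' \eqn{\hat U_Y = \sigma_Y^2 / (2E)}, the maximum allowable strain-energy
#' density of a material point (N.mm/mm^3 in the mm-N-MPa system).
#'
#' @param E Young's modulus, MPa.
#' @param sigmaY yield stress, MPa.
#' @return energy density, N.mm/mm^3.
#' @export
yieldEnergyDensity <- function(E, sigmaY) {
  if (any(E <= 0)) stop("E must be positive")
  sigmaY^2 / (2 * E)
}

#' Group elements into discrete material bins
#'
#' Converts per-element HU to ash density, partitions the density range into
#' \code{nBins} equal-width intervals, and assigns each nonempty bin the mean
#' ash density of its member elements as representative density, from which E
#' and sigma_Y follow by the power laws.  Binning is performed on density
#' (the physical variable entering the constitutive laws) rather than raw HU.
#'
#' @param x a \linkS4class{TetMesh} or a numeric vector of element HU.
#' @param nBins requested number of bins (default 50, the converged value for
#'   femur models).
#' @param nu Poisson ratio assigned to every bin (default 0.4).
#' @param clamp lower density bound passed to \code{\link{ashDensityFromHU}}.
#' @return a \linkS4class{MaterialTable}; empty bins are dropped, so the
#'   number of realized bins is at most \code{nBins}.
#' @examples
#' binMaterials(c(100, 500, 2000), nBins = 2)
#' @export
binMaterials <- function(x, nBins = 50L, nu = 0.4, clamp = 0.01) {
  hu <- if (is(x, "TetMesh")) elementHU(x) else as.numeric(x)
  if (length(hu) == 0) stop("cannot bin an empty element set")
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be >= 1")
  if (nu <= 0 || nu >= 0.5) stop("nu must lie in (0, 0.5)")
  rho <- ashDensityFromHU(hu, clamp = clamp)
  rng <- range(rho)
  if (rng[1] == rng[2]) {
    idx <- rep(1L, length(rho))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = nBins + 1)
    idx <- findInterval(rho, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  occupied <- sort(unique(idx))
  repDensity <- vapply(occupied, function(b) mean(rho[idx == b]), numeric(1))
  ord <- order(repDensity)
  occupied <- occupied[ord]
  repDensity <- repDensity[ord]
  remap <- integer(max(occupied))
  remap[occupied] <- seq_along(occupied)
  bins <- data.frame(bin_id = seq_along(occupied),
                     density = repDensity,
                     E = youngModulus(repDensity),
                     sigma_Y = yieldStress(repDensity),
                     nu = nu)
  new("MaterialTable", bins = bins, elementBin = remap[idx],
      nBins = nBins)
}

#' MaterialTable accessors
#'
#' @param x a \linkS4class{MaterialTable}.
#' @return \code{materialBins}: the bin data.frame; \code{elementBins}: bin
#'   index per element; \code{elementE} / \code{elementYieldStress}:
#'   per-element E (MPa) and sigma_Y (MPa) looked up through the bins.
#' @name MaterialTable-accessors
NULL

#' @rdname MaterialTable-accessors
#' @export
setMethod("materialBins", "MaterialTable", function(x) x@bins)
#' @rdname MaterialTable-accessors
#' @export
setMethod("elementBins", "MaterialTable", function(x) x@elementBin)
#' @rdname MaterialTable-accessors
#' @export
setMethod("elementE", "MaterialTable",
          function(x) x@bins$E[x@elementBin])
#' @rdname MaterialTable-accessors
#' @export
setMethod("elementYieldStress", "MaterialTable",
          function(x) x@bins$sigma_Y[x@elementBin])

setMethod("show", "MaterialTable", function(object) {
  cat("MaterialTable:", nrow(object@bins), "bins (", object@nBins,
      "requested ) over", length(object@elementBin), "elements\n")
  cat(sprintf("  density %.4f-%.4f g/cm^3, E %.0f-%.0f MPa, nu %.2f\n",
              min(object@bins$density), max(object@bins$density),
              min(object@bins$E), max(object@bins$E), object@bins$nu[1]))
})

#' Isotropic elasticity matrix
#'
#' The 6 x 6 isotropic stress-strain matrix in Voigt order
#' (xx, yy, zz, xy, yz, zx) with engineering shear strains:
#' \eqn{E/((1+\nu)(1-2\nu))} times the matrix with \eqn{1-\nu} on the normal
#' diagonal, \eqn{\nu} off-diagonal in the upper 3 x 3 block and
#' \eqn{1/2-\nu} on the shear diagonal.  Symmetric positive definite for
#' \eqn{0 < \nu < 1/2}.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio in (0, 0.5).
#' @return 6 x 6 numeric matrix, MPa.
#' @examples
#' elasticityMatrix(1, 0.4)[1, 1]   # (1 - nu)/((1 + nu)(1 - 2 nu)) = 15/7
#' @export
elasticityMatrix <- function(E, nu) {
  if (E <= 0) stop("E must be positive")
  if (nu <= 0 || nu >= 0.5)
    stop("nu must lie in (0, 0.5); the factor is singular at nu = 0.5")
  A <- matrix(nu, 3, 3)
  diag(A) <- 1 - nu
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- A
  D[4:6, 4:6] <- diag(rep(0.5 - nu, 3))
  E / ((1 + nu) * (1 - 2 * nu)) * D
}

#' Write a material table to CSV
#'
#' @param materials a \linkS4class{MaterialTable}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMaterialCSV <- function(materials, path) {
  write.csv(materialBins(materials), path, row.names = FALSE)
  invisible(path)
}
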