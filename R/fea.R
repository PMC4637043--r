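#' Single-leg stance joint force
#'
#' Peak hip joint contact force during single-leg stance, taken as 2.5 times
#' body weight and applied as a distributed load on the femoral head along
#' the shaft axis.
#'
#' @param w body weight, N; positive.
#' @return force magnitude, N.
#' @examples
#' stanceForce(700)   # 1750 N
#' @export
stanceForce <- function(w) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("body weight must be positive")
  2.5 * w
}

#' Sideways-fall impact force
#'
#' Peak impact force on the greater trochanter during a sideways fall from
#' standing height, \eqn{F = 8.25\,w\,(h/170)^{1/2}} with body weight w in N
#' and height h in cm.
#'
#' @param w body weight, N; positive.
#' @param h subject height, cm; positive.
#' @return force magnitude, N.
#' @examples
#' impactForce(600, 170)   # 4950 N
#' @export
impactForce <- function(w, h) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("body weight must be positive")
  if (any(!is.finite(h)) || any(h <= 0)) stop("height must be positive")
  8.25 * w * sqrt(h / 170)
}

# Surface nodes within radius of a point.
.captureNodes <- function(mesh, point, radius, surface = NULL) {
  if (is.null(surface)) surface <- .surfaceNodes(mesh)
  d <- sweep(mesh@nodes[surface, , drop = FALSE], 2, point)
  surface[sqrt(rowSums(d * d)) <= radius]
}

# Femoral-head contact patch: surface nodes on the head sphere (distance to
# the fitted centre within [0.9, capture] of the radius) lying on the
# hemisphere that faces the contact (the side the load or reaction comes
# from, i.e. (p - C) . towards >= 0).  Restricting to the sphere keeps
# neck-surface nodes near the head-neck junction out of the set.
.headContactNodes <- function(mesh, centre, radius, towards, capture,
                              surface = NULL) {
  if (is.null(surface)) surface <- .surfaceNodes(mesh)
  d <- sweep(mesh@nodes[surface, , drop = FALSE], 2, centre)
  r <- sqrt(rowSums(d * d))
  onSphere <- r >= 0.9 * radius & r <= capture * radius
  facing <- (d %*% towards) >= 0
  surface[onSphere & facing]
}

#' Build the stance or fall load case
#'
#' Translates the physiological configuration into nodal forces and supports:
#' \describe{
#'   \item{stance}{total force \code{stanceForce(w)} split equally over the
#'     femoral-head surface nodes, directed distally along the shaft axis;
#'     distal-end nodes fully fixed.}
#'   \item{fall}{total force \code{impactForce(w, h)} split equally over the
#'     greater-trochanter surface nodes, directed perpendicular to the shaft
#'     axis within the neck-shaft plane (pointing medially, towards the
#'     head); distal-end nodes fully fixed and femoral-head surface nodes
#'     constrained along the load direction only.}
#' }
#' Node sets are geometric captures around the landmarks: head = surface
#' nodes on the head sphere (within \code{headCapture} times the fitted
#' radius of the head centre) restricted to the contact hemisphere facing
#' the applied load or reaction, trochanter = surface nodes within
#' \code{trochCapture} mm of the
#' greater-trochanter landmark, distal = nodes within \code{distalTol} mm of
#' the distal end plane.
#'
#' @param mesh a \linkS4class{TetMesh} with femoral landmarks.
#' @param configuration \code{"stance"} or \code{"fall"}.
#' @param w body weight, N.
#' @param h height, cm (used by the fall case).
#' @param axes optional \linkS4class{FemoralAxes}; computed from the mesh
#'   when missing.
#' @param headCapture multiple of the head radius for the head node capture.
#' @param trochCapture capture radius around the greater trochanter, mm.
#' @param distalTol thickness of the distal fixation band, mm.
#' @return a \linkS4class{LoadCase}.
#' @export
buildLoadCase <- function(mesh, configuration = c("stance", "fall"),
                          w, h = NA_real_, axes = NULL,
                          headCapture = 1.05, trochCapture = 12,
                          distalTol = 5) {
  configuration <- match.arg(configuration)
  lm <- mesh@landmarks
  need <- c("head_centre", "greater_trochanter", "distal_end_centre")
  if (!all(need %in% names(lm)))
    stop("mesh landmarks must include ", paste(need, collapse = ", "))
  if (is.null(axes)) axes <- femoralAxes(mesh)
  surface <- .surfaceNodes(mesh)
  shaft <- axes@shaftDir                          # proximal
  distal <- lm$distal_end_centre
  t <- as.vector(sweep(mesh@nodes, 2, distal) %*% shaft)
  distalNodes <- which(t <= distalTol)
  if (length(distalNodes) == 0) stop("empty distal fixation node set")

  if (configuration == "stance") {
    F <- stanceForce(w)
    dir <- -shaft
    headNodes <- .headContactNodes(mesh, axes@headCentre, axes@headRadius,
                                   towards = -dir, capture = headCapture,
                                   surface = surface)
    loaded <- setdiff(headNodes, distalNodes)
    if (length(loaded) == 0) stop("empty femoral-head load node set")
    dirNodes <- integer()
    dirDir <- numeric()
  } else {
    if (!is.finite(h)) stop("the fall case needs the subject height h (cm)")
    F <- impactForce(w, h)
    trochNodes <- .captureNodes(mesh, lm$greater_trochanter, trochCapture,
                                surface)
    loaded <- setdiff(trochNodes, distalNodes)
    if (length(loaded) == 0) stop("empty greater-trochanter load node set")
    medial <- axes@headCentre - lm$greater_trochanter
    dir <- .unit(medial - sum(medial * shaft) * shaft)
    headNodes <- .headContactNodes(mesh, axes@headCentre, axes@headRadius,
                                   towards = dir, capture = headCapture,
                                   surface = surface)
    dirNodes <- setdiff(headNodes, union(distalNodes, loaded))
    dirDir <- dir
  }
  forces <- matrix(rep(dir * (F / length(loaded)), each = length(loaded)),
                   ncol = 3)
  new("LoadCase", configuration = configuration, bodyWeight = w,
      height = h, totalForce = F, direction = dir,
      loadedNodes = as.integer(loaded), nodeForces = forces,
      fixedDofs = as.integer(outer(3L * (distalNodes - 1L), 1:3, `+`)),
      directionalNodes = as.integer(dirNodes), directionalDir = dirDir)
}

#' Axial end-load case for validation fixtures
#'
#' Loads one end face of a bar or cylinder fixture with a total force along
#' the axis, weighting each node by its tributary surface area (consistent
#' with a uniform traction), and supports the opposite face with rollers
#' (axial fixity plus the minimal in-plane pins removing rigid-body modes),
#' so the uniform uniaxial stress state is reproduced exactly by linear
#' tetrahedra.
#'
#' @param mesh a fixture \linkS4class{TetMesh} with \code{end_a_centre} /
#'   \code{end_b_centre} landmarks (axis along z).
#' @param totalForce axial force applied at the \code{end_b} face, N
#'   (positive = tension).
#' @param clamp if \code{TRUE}, fully fix the \code{end_a} face instead of
#'   using rollers.
#' @return a \linkS4class{LoadCase} with configuration \code{"custom"}.
#' @export
endLoadCase <- function(mesh, totalForce, clamp = FALSE) {
  lm <- mesh@landmarks
  if (!all(c("end_a_centre", "end_b_centre") %in% names(lm)))
    stop("mesh must carry end_a_centre / end_b_centre landmarks")
  axis <- .unit(lm$end_b_centre - lm$end_a_centre)
  zb <- sum(lm$end_b_centre * axis)
  za <- sum(lm$end_a_centre * axis)
  t <- as.vector(mesh@nodes %*% axis)
  tol <- 1e-6 * (zb - za)
  endB <- which(abs(t - zb) <= tol)
  endA <- which(abs(t - za) <= tol)
  if (!length(endB) || !length(endA)) stop("could not locate the end faces")

  bf <- .boundaryFaces(mesh@elements)
  onB <- matrix(bf$faces %in% endB, ncol = 3)
  faceB <- bf$faces[rowSums(onB) == 3L, , drop = FALSE]
  wts <- numeric(nrow(mesh@nodes))
  for (k in seq_len(nrow(faceB))) {
    p <- mesh@nodes[faceB[k, ], ]
    a2 <- .norm3(.cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])) / 2
    wts[faceB[k, ]] <- wts[faceB[k, ]] + a2 / 3
  }
  loaded <- which(wts > 0)
  forces <- (wts[loaded] / sum(wts[loaded])) %*% t(axis) * totalForce

  if (clamp) {
    fixedDofs <- as.integer(outer(3L * (endA - 1L), 1:3, `+`))
  } else {
    axialAxis <- which.max(abs(axis))
    inplane <- setdiff(1:3, axialAxis)
    fixedDofs <- 3L * (endA - 1L) + axialAxis
    pts <- mesh@nodes[endA, inplane, drop = FALSE]
    pinA <- endA[which.min(rowSums(pts^2))]
    dA <- sweep(pts, 2, mesh@nodes[pinA, inplane])
    # second pin: same coordinate along the second in-plane axis as pinA,
    # farthest along the first, so the exact uniaxial field stays admissible
    same <- which(abs(dA[, 2]) <= tol)
    pinB <- endA[same[which.max(abs(dA[same, 1]))]]
    fixedDofs <- c(fixedDofs,
                   3L * (pinA - 1L) + inplane,
                   3L * (pinB - 1L) + inplane[2])
  }
  new("LoadCase", configuration = "custom", bodyWeight = NA_real_,
      height = NA_real_, totalForce = abs(totalForce),
      direction = sign(totalForce) * axis,
      loadedNodes = as.integer(loaded), nodeForces = forces,
      fixedDofs = as.integer(fixedDofs),
      directionalNodes = integer(), directionalDir = numeric())
}

# Strain-displacement matrix (6 x 12, Voigt engineering shear) and volume of
# one linear tetrahedron.
.tetBMatrix <- function(p) {
  M <- rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])
  V <- det(M) / 6
  Minv <- solve(M)                      # grad N_{a+1} = Minv[, a]
  G <- rbind(-rowSums(Minv), t(Minv))
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- G[a, 1]
    B[2, c0 + 2] <- G[a, 2]
    B[3, c0 + 3] <- G[a, 3]
    B[4, c0 + 1] <- G[a, 2]; B[4, c0 + 2] <- G[a, 1]
    B[5, c0 + 2] <- G[a, 3]; B[5, c0 + 3] <- G[a, 2]
    B[6, c0 + 1] <- G[a, 3]; B[6, c0 + 3] <- G[a, 1]
  }
  list(B = B, V = V)
}

#' Solve the linear elastostatic problem
#'
#' Assembles the global stiffness matrix from constant-strain tetrahedra
#' (\eqn{k_e = V_e B_e^T D_e B_e} with the binned elasticity matrix
#' \eqn{D_e}), applies the load case constraints (fully fixed DOFs eliminated;
#' single-direction constraints via Lagrange multipliers) and solves
#' \eqn{K d = f} with a sparse direct factorization.  Per-element strain,
#' stress, strain-energy density \eqn{\frac12 \varepsilon^T D \varepsilon}
#' and the von Mises equivalent fields are recovered from the displacement
#' field.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param materials a \linkS4class{MaterialTable} for the mesh.
#' @param load a \linkS4class{LoadCase}.
#' @return an \linkS4class{FESolution}.  The Clapeyron identity
#'   \code{totalStrainEnergy(x) == externalWork(x)} holds to solver
#'   precision.
#' @export
solveFE <- function(mesh, materials, load) {
  validObject(load)
  if (length(materials@elementBin) != nrow(mesh@elements))
    stop("materials were binned for a different mesh")
  nodesM <- mesh@nodes
  el <- mesh@elements
  m <- nrow(el)
  ndof <- 3L * nrow(nodesM)

  vols <- .tetVolumes(nodesM, el)
  if (any(vols <= 0))
    stop("element ", which(vols <= 0)[1], " has nonpositive volume")

  bins <- materials@bins
  Dlist <- lapply(seq_len(nrow(bins)),
                  function(b) elasticityMatrix(bins$E[b], bins$nu[b]))
  ebin <- materials@elementBin

  Blist <- vector("list", m)
  ii <- integer(144L * m); jj <- integer(144L * m); xx <- numeric(144L * m)
  pos <- 0L
  dofIdx <- function(nodesOf) as.vector(t(outer(3L * (nodesOf - 1L), 1:3, `+`)))
  for (e in seq_len(m)) {
    bv <- .tetBMatrix(nodesM[el[e, ], ])
    Blist[[e]] <- bv$B
    ke <- bv$V * crossprod(bv$B, Dlist[[ebin[e]]] %*% bv$B)
    dofs <- dofIdx(el[e, ])
    ii[pos + 1:144] <- rep(dofs, times = 12)
    jj[pos + 1:144] <- rep(dofs, each = 12)
    xx[pos + 1:144] <- as.vector(ke)
    pos <- pos + 144L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))

  f <- numeric(ndof)
  ldofs <- as.vector(t(outer(3L * (load@loadedNodes - 1L), 1:3, `+`)))
  f[ldofs] <- as.vector(t(load@nodeForces))

  fixed <- sort(unique(load@fixedDofs))
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- K[free, free, drop = FALSE]
  ff <- f[free]
  d <- numeric(ndof)

  nlag <- length(load@directionalNodes)
  if (nlag > 0) {
    # one row per constrained node: u . dir = 0
    freePos <- integer(ndof)
    freePos[free] <- seq_along(free)
    cdofs <- outer(3L * (load@directionalNodes - 1L), 1:3, `+`)
    if (any(freePos[cdofs] == 0))
      stop("directionally constrained nodes overlap fixed DOFs")
    Cmat <- Matrix::sparseMatrix(
      i = rep(seq_len(nlag), 3),
      j = as.vector(freePos[cdofs]),
      x = rep(load@directionalDir, each = nlag),
      dims = c(nlag, length(free)))
    A <- rbind(cbind(Kff, Matrix::t(Cmat)),
               cbind(Cmat, Matrix::sparseMatrix(i = integer(), j = integer(),
                                                x = numeric(),
                                                dims = c(nlag, nlag))))
    rhs <- c(ff, numeric(nlag))
    sol <- tryCatch(Matrix::solve(A, rhs),
                    error = function(e) stop("singular constrained system: ",
                                             conditionMessage(e)))
    d[free] <- sol[seq_along(free)]
  } else {
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                   error = function(e)
                     stop("stiffness matrix is not positive definite after ",
                          "constraints; rigid-body modes remain (",
                          conditionMessage(e), ")"))
    d[free] <- as.vector(Matrix::solve(ch, ff))
  }
  res <- as.vector(Kff %*% d[free]) - ff
  relres <- sqrt(sum(res^2)) / max(sqrt(sum(ff^2)), .Machine$double.eps)
  if (nlag == 0 && relres > 1e-8)
    stop(sprintf(paste("system appears singular (relative residual %.2e):",
                       "unconstrained rigid-body modes remain"), relres))

  disp <- matrix(d, ncol = 3, byrow = TRUE)
  strain <- matrix(0, m, 6)
  stress <- matrix(0, m, 6)
  for (e in seq_len(m)) {
    de <- d[dofIdx(el[e, ])]
    eps <- as.vector(Blist[[e]] %*% de)
    strain[e, ] <- eps
    stress[e, ] <- as.vector(Dlist[[ebin[e]]] %*% eps)
  }
  u <- 0.5 * rowSums(strain * stress)
  nu <- bins$nu[ebin]
  total <- sum(u * vols)
  new("FESolution", displacements = disp, strain = strain, stress = stress,
      energyDensity = u,
      vmStress = .vonMisesStressVoigt(stress),
      vmStrain = .vonMisesStrainVoigt(strain, nu),
      totalEnergy = total, externalWork = 0.5 * sum(f * d),
      volumes = vols, load = load)
}

# von Mises stress from Voigt stress rows (shear entries are tensor shears
# for stress).
.vonMisesStressVoigt <- function(s) {
  sqrt(pmax(0,
    s[, 1]^2 + s[, 2]^2 + s[, 3]^2 -
    s[, 1] * s[, 2] - s[, 2] * s[, 3] - s[, 3] * s[, 1] +
    3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2)))
}

# Equivalent (von Mises) strain in the effective-Poisson-ratio convention:
# (1/(1+nu')) * sqrt( (1/2) * sum_{i<j} (eps_i - eps_j)^2 ) over principal
# strains, evaluated through tensor invariants (engineering shears halved).
.vonMisesStrainVoigt <- function(eps, nuEff) {
  exy <- eps[, 4] / 2; eyz <- eps[, 5] / 2; ezx <- eps[, 6] / 2
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  tr2 <- eps[, 1]^2 + eps[, 2]^2 + eps[, 3]^2 +
    2 * (exy^2 + eyz^2 + ezx^2)
  sqrt(pmax(0, (3 * tr2 - tr^2) / 2)) / (1 + nuEff)
}

#' FESolution accessors
#'
#' @param x an \linkS4class{FESolution}.
#' @return \code{displacements}: n x 3 nodal displacements (mm);
#'   \code{elementStrain} / \code{elementStress}: m x 6 Voigt fields
#'   (engineering shear strains); \code{energyDensity}: strain-energy density
#'   per element (N.mm/mm^3); \code{totalStrainEnergy} /
#'   \code{externalWork}: N.mm.
#' @name FESolution-accessors
NULL

#' @rdname FESolution-accessors
#' @export
setMethod("displacements", "FESolution", function(x) x@displacements)
#' @rdname FESolution-accessors
#' @export
setMethod("elementStrain", "FESolution", function(x) x@strain)
#' @rdname FESolution-accessors
#' @export
setMethod("elementStress", "FESolution", function(x) x@stress)
#' @rdname FESolution-accessors
#' @export
setMethod("energyDensity", "FESolution", function(x) x@energyDensity)
#' @rdname FESolution-accessors
#' @export
setMethod("totalStrainEnergy", "FESolution", function(x) x@totalEnergy)
#' @rdname FESolution-accessors
#' @export
setMethod("externalWork", "FESolution", function(x) x@externalWork)

#' Von Mises equivalent fields
#'
#' Per-element von Mises stress (from the deviatoric stress) and equivalent
#' strain, the latter computed from the principal strains as
#' \eqn{\frac{1}{1+\nu'}\sqrt{\frac12[(\varepsilon_1-\varepsilon_2)^2+
#' (\varepsilon_2-\varepsilon_3)^2+(\varepsilon_3-\varepsilon_1)^2]}} with
#' the material Poisson ratio as effective ratio \eqn{\nu'}.
#'
#' @param x an \linkS4class{FESolution}.
#' @return numeric vector, one value per element (MPa for stress).
#' @name vonMisesFields
NULL

#' @rdname vonMisesFields
#' @export
setMethod("vonMisesStress", "FESolution", function(x) x@vmStress)
#' @rdname vonMisesFields
#' @export
setMethod("vonMisesStrain", "FESolution", function(x) x@vmStrain)

setMethod("show", "FESolution", function(object) {
  cat("FESolution:", nrow(object@displacements), "nodes,",
      nrow(object@strain), "elements (", object@load@configuration, ")\n")
  cat(sprintf("  max |u| %.4g mm, total strain energy %.4g N.mm\n",
              max(sqrt(rowSums(object@displacements^2))),
              object@totalEnergy))
})
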