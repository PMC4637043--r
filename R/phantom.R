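#' Create a phantom specification
#'
#' Convenience constructor for \linkS4class{PhantomSpec}; unspecified
#' arguments keep the class defaults (a generic adult proximal femur).
#'
#' @param ... slot values, e.g. \code{neckShaftAngle = 120}, \code{seed = 7L}.
#' @return a validated \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec(neckShaftAngle = 125, huNoiseSD = 0)
#' @export
phantomSpec <- function(...) {
  args <- list(...)
  if ("seed" %in% names(args)) args$seed <- as.integer(args$seed)
  do.call(new, c(list("PhantomSpec"), args))
}

# ---- implicit geometry -----------------------------------------------------

# Signed distance to a sphere, vectorized over rows of P.
.sdSphere <- function(P, centre, r) {
  d <- sweep(P, 2, centre)
  sqrt(rowSums(d * d)) - r
}

# Signed distance to a capped cylinder from point p0 along unit dir, length L.
# radiusFun maps the axial coordinate t in [0, L] to the local radius; for a
# constant radius this is the exact distance, for a slowly varying radius a
# close approximation (adequate for classification and projection).
.sdCappedCylinder <- function(P, p0, dir, L, radiusFun) {
  d <- sweep(P, 2, p0)
  t <- d %*% dir
  radial <- d - t %*% t(dir)
  dr <- sqrt(rowSums(radial * radial)) - radiusFun(pmin(pmax(t, 0), L))
  dz <- abs(t - L / 2) - L / 2
  pmin(pmax(dr, dz), 0) + sqrt(pmax(dr, 0)^2 + pmax(dz, 0)^2)
}

# Femur phantom implicit solid (negative inside) and its reference geometry.
.femurGeometry <- function(spec) {
  J <- c(0, 0, spec@shaftLength)               # neck-shaft junction
  beta <- (180 - spec@neckShaftAngle) * pi / 180
  nhat <- c(sin(beta), 0, cos(beta))           # junction -> head direction
  C <- J + spec@neckLength * nhat
  u0 <- spec@waistPosition * spec@neckLength   # waist position from junction
  neckRadiusAt <- function(t)
    spec@neckRadius - spec@waistDepth * exp(-((t - u0) / spec@waistWidth)^2)
  trochCentre <- c(-spec@trochLateral, 0, spec@shaftLength + spec@trochProximal)
  F <- function(P) {
    P <- matrix(P, ncol = 3)
    sd <- pmin(
      .sdCappedCylinder(P, c(0, 0, 0), c(0, 0, 1), spec@shaftLength,
                        function(t) spec@shaftRadius),
      .sdCappedCylinder(P, J, nhat, spec@neckLength, neckRadiusAt),
      .sdSphere(P, C, spec@headRadius))
    if (spec@trochRadius > 0)
      sd <- pmin(sd, .sdSphere(P, trochCentre, spec@trochRadius))
    sd
  }
  lo <- pmin(c(-spec@shaftRadius, -spec@shaftRadius, 0),
             C - spec@headRadius, pmin(J, C) - spec@neckRadius)
  hi <- pmax(c(spec@shaftRadius, spec@shaftRadius, spec@shaftLength),
             C + spec@headRadius, pmax(J, C) + spec@neckRadius)
  if (spec@trochRadius > 0) {
    lo <- pmin(lo, trochCentre - spec@trochRadius)
    hi <- pmax(hi, trochCentre + spec@trochRadius)
  }
  list(F = F, junction = J, neckDir = nhat, headCentre = C,
       waistCentre = J + u0 * nhat, trochCentre = trochCentre,
       bbox = rbind(lo, hi))
}

# ---- background-grid tetrahedralization ------------------------------------

# Kuhn subdivision of a cube grid into 6 tetrahedra per cell, keeping the
# tetrahedra whose centroid lies inside the implicit solid (F < 0).
.gridTets <- function(F, bbox, s) {
  lo <- bbox[1, ] - 0.5 * s
  ext <- (bbox[2, ] + 0.5 * s) - lo
  nc <- pmax(1L, as.integer(ceiling(ext / s)))
  nx <- nc[1]; ny <- nc[2]; nz <- nc[3]
  gx <- lo[1] + s * (0:nx); gy <- lo[2] + s * (0:ny); gz <- lo[3] + s * (0:nz)
  nodes <- cbind(rep(gx, times = (ny + 1) * (nz + 1)),
                 rep(rep(gy, each = nx + 1), times = nz + 1),
                 rep(gz, each = (nx + 1) * (ny + 1)))
  ox <- 1L; oy <- nx + 1L; oz <- (nx + 1L) * (ny + 1L)
  ix <- rep(0:(nx - 1), times = ny * nz)
  iy <- rep(rep(0:(ny - 1), each = nx), times = nz)
  iz <- rep(0:(nz - 1), each = nx * ny)
  base <- 1L + ix * ox + iy * oy + iz * oz
  perms <- list(c(ox, oy, oz), c(ox, oz, oy), c(oy, ox, oz),
                c(oy, oz, ox), c(oz, ox, oy), c(oz, oy, ox))
  elems <- vector("list", 6L)
  for (k in seq_along(perms)) {
    p <- perms[[k]]
    elems[[k]] <- cbind(base, base + p[1], base + p[1] + p[2],
                        base + p[1] + p[2] + p[3])
  }
  elements <- do.call(rbind, elems)
  storage.mode(elements) <- "integer"
  keep <- F(.tetCentroids(nodes, elements)) < 0
  elements <- elements[keep, , drop = FALSE]
  if (nrow(elements) == 0)
    stop("implicit solid does not intersect the background grid")
  cm <- .compactMesh(nodes, elements)
  cm$elements <- .orientTets(cm$nodes, cm$elements)
  keepEl <- .largestComponent(cm$nodes, cm$elements)
  cm$elements <- cm$elements[keepEl, , drop = FALSE]
  .compactMesh(cm$nodes, cm$elements)
}

# Project boundary nodes onto the zero level set of F (Newton steps along the
# numerical gradient), with a hard cap on the total displacement so that the
# mesh edge-length bound survives, and reversal of any projection that would
# degenerate an incident tetrahedron.
.snapBoundary <- function(nodes, elements, F, cap, h) {
  bn0 <- unique(as.vector(.boundaryFaces(elements)$faces))
  orig <- nodes[bn0, , drop = FALSE]
  P <- orig
  for (it in 1:4) {
    f <- as.vector(F(P))
    g <- matrix(0, nrow(P), 3)
    for (a in 1:3) {
      Pp <- P; Pp[, a] <- Pp[, a] + h
      Pm <- P; Pm[, a] <- Pm[, a] - h
      g[, a] <- (as.vector(F(Pp)) - as.vector(F(Pm))) / (2 * h)
    }
    gn2 <- rowSums(g * g)
    gn2[gn2 < 1e-12] <- Inf
    P <- P - (f / gn2) * g
    d <- P - orig
    dn <- sqrt(rowSums(d * d))
    over <- dn > cap
    if (any(over))
      P[over, ] <- orig[over, , drop = FALSE] +
        d[over, , drop = FALSE] * (cap / dn[over])
  }
  nodes[bn0, ] <- P
  minVol <- 0.05 * (cap / 0.4)^3 / 6      # fraction of a grid-cell tetrahedron
  moved <- bn0
  repeat {
    v <- .tetVolumes(nodes, elements)
    bad <- which(v <= minVol)
    if (!length(bad)) break
    badNodes <- intersect(unique(as.vector(elements[bad, , drop = FALSE])), moved)
    if (!length(badNodes)) break
    nodes[badNodes, ] <- orig[match(badNodes, bn0), , drop = FALSE]
    moved <- setdiff(moved, badNodes)
  }
  nodes
}

# ---- phantom generator -----------------------------------------------------

#' Generate a synthetic proximal-femur mesh
#'
#' Builds a watertight tetrahedral mesh of the union shaft + angled neck +
#' spherical head defined by \code{spec}: a background cube grid (Kuhn 6-tet
#' subdivision) is classified against the implicit solid and boundary nodes
#' are projected onto the surface.  Elements whose centroid lies within
#' \code{corticalThickness} of the outer surface receive \code{corticalHU},
#' interior elements \code{cancellousHU}; seeded Gaussian noise (clamped below
#' at 1 HU) is added on top.  Landmarks (head centre, greater and lesser
#' trochanter, distal end centre) and the construction ground truth
#' (neck-shaft angle, axes, waist position) are stored with the mesh.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{TetMesh} with maximum element edge length
#'   \code{<= spec@targetEdgeLength}.
#' @examples
#' mesh <- generatePhantom(phantomSpec(targetEdgeLength = 14, huNoiseSD = 0))
#' mesh
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  if (spec@corticalThickness >= min(spec@shaftRadius, spec@headRadius))
    stop("infeasible geometry: corticalThickness (", spec@corticalThickness,
         " mm) must be smaller than every local radius")
  geo <- .femurGeometry(spec)
  s <- spec@targetEdgeLength / (sqrt(3) + 0.8)
  gm <- .gridTets(geo$F, geo$bbox, s)
  gm$nodes <- .snapBoundary(gm$nodes, gm$elements, geo$F,
                            cap = 0.4 * s, h = 1e-4 * s)
  gm$elements <- .orientTets(gm$nodes, gm$elements)

  depth <- -as.vector(geo$F(.tetCentroids(gm$nodes, gm$elements)))
  hu <- ifelse(depth <= spec@corticalThickness,
               spec@corticalHU, spec@cancellousHU)
  if (spec@huNoiseSD > 0) {
    runState <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(runState)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", runState, envir = globalenv())
    })
    set.seed(spec@seed)
    hu <- pmax(hu + rnorm(length(hu), 0, spec@huNoiseSD), 1)
  }

  # The greater trochanter lies on the lateral surface opposite the femoral
  # head along the neck axis (the sideways-fall impact point), found by
  # casting the neck-axis ray beyond the junction until it exits the solid.
  tExit <- spec@neckLength
  for (t in seq(spec@neckLength, spec@neckLength + 4 * spec@shaftRadius,
                by = 0.25)) {
    if (geo$F(rbind(geo$headCentre - t * geo$neckDir)) > 0) break
    tExit <- t
  }
  landmarks <- list(
    head_centre = geo$headCentre,
    greater_trochanter = as.vector(geo$headCentre - tExit * geo$neckDir),
    lesser_trochanter = c(spec@shaftRadius, 0, spec@shaftLength - 15),
    distal_end_centre = c(0, 0, 0))
  groundTruth <- list(
    neck_shaft_angle = spec@neckShaftAngle,
    neck_axis = geo$neckDir,          # junction -> head, unit
    shaft_axis = c(0, 0, 1),          # distal -> proximal, unit
    head_centre = geo$headCentre,
    head_radius = spec@headRadius,
    junction = geo$junction,
    waist_centre = geo$waistCentre)
  tetMesh(gm$nodes, gm$elements, hu, landmarks, groundTruth)
}

# ---- analytic fixtures -----------------------------------------------------

#' Rectangular bar fixture
#'
#' Structured tetrahedral mesh of a \code{length} x \code{side} x \code{side}
#' bar (axis along z, one corner at the origin) with uniform HU, used to
#' validate the solver against the closed-form axial solution
#' delta = F L / (E A).  The summed element volumes equal the analytic volume
#' exactly.
#'
#' @param length,side bar dimensions, mm.
#' @param edge maximum element edge length, mm.
#' @param hu uniform Hounsfield value.
#' @return a \linkS4class{TetMesh} with landmarks \code{end_a_centre} (z = 0)
#'   and \code{end_b_centre} (z = length).
#' @export
generateBarFixture <- function(length, side, edge, hu) {
  if (length <= 0 || side <= 0 || edge <= 0)
    stop("bar dimensions and edge length must be positive")
  if (edge > min(length, side))
    stop("edge length exceeds the smallest bar dimension")
  cell <- edge / sqrt(3)
  n <- pmax(1L, as.integer(ceiling(c(side, side, length) / cell)))
  gx <- seq(0, side, length.out = n[1] + 1)
  gy <- seq(0, side, length.out = n[2] + 1)
  gz <- seq(0, length, length.out = n[3] + 1)
  nodes <- cbind(rep(gx, times = (n[2] + 1) * (n[3] + 1)),
                 rep(rep(gy, each = n[1] + 1), times = n[3] + 1),
                 rep(gz, each = (n[1] + 1) * (n[2] + 1)))
  ox <- 1L; oy <- n[1] + 1L; oz <- (n[1] + 1L) * (n[2] + 1L)
  ix <- rep(0:(n[1] - 1), times = n[2] * n[3])
  iy <- rep(rep(0:(n[2] - 1), each = n[1]), times = n[3])
  iz <- rep(0:(n[3] - 1), each = n[1] * n[2])
  base <- 1L + ix * ox + iy * oy + iz * oz
  perms <- list(c(ox, oy, oz), c(ox, oz, oy), c(oy, ox, oz),
                c(oy, oz, ox), c(oz, ox, oy), c(oz, oy, ox))
  elements <- do.call(rbind, lapply(perms, function(p)
    cbind(base, base + p[1], base + p[1] + p[2], base + p[1] + p[2] + p[3])))
  storage.mode(elements) <- "integer"
  tetMesh(nodes, elements, rep(hu, nrow(elements)),
          landmarks = list(end_a_centre = c(side / 2, side / 2, 0),
                           end_b_centre = c(side / 2, side / 2, length)),
          groundTruth = list(type = "bar", length = length, side = side))
}

# Triangle strip between two concentric vertex rings sorted by angle.
.annulusTris <- function(innerIdx, innerAng, outerIdx, outerAng) {
  ni <- base::length(innerIdx); no <- base::length(outerIdx)
  if (ni == 1L) {                        # fan from the centre point
    o2 <- c(seq_len(no)[-1], 1L)
    return(cbind(innerIdx, outerIdx, outerIdx[o2]))
  }
  iu <- c(innerAng, innerAng[1] + 2 * pi)
  ou <- c(outerAng, outerAng[1] + 2 * pi)
  tris <- matrix(0L, ni + no, 3L)
  i <- 1L; o <- 1L; t <- 0L
  while (i <= ni || o <= no) {
    advOuter <- if (o > no) FALSE else if (i > ni) TRUE else ou[o + 1] <= iu[i + 1]
    t <- t + 1L
    wi <- ((i - 1L) %% ni) + 1L; wo <- ((o - 1L) %% no) + 1L
    if (advOuter) {
      wo2 <- (wo %% no) + 1L
      tris[t, ] <- c(innerIdx[wi], outerIdx[wo], outerIdx[wo2])
      o <- o + 1L
    } else {
      wi2 <- (wi %% ni) + 1L
      tris[t, ] <- c(innerIdx[wi], outerIdx[wo], innerIdx[wi2])
      i <- i + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

# Planar disk triangulation: concentric rings merged ring-by-ring.
.diskTriangulation <- function(radius, edge2d) {
  K <- max(1L, as.integer(ceiling(radius / edge2d)))
  pts <- matrix(c(0, 0), 1, 2)
  ringIdx <- list(1L)
  ringAng <- list(0)
  for (k in seq_len(K)) {
    rk <- radius * k / K
    nk <- max(6L, as.integer(ceiling(2 * pi * rk / edge2d)))
    ang <- 2 * pi * (0:(nk - 1)) / nk
    ringIdx[[k + 1]] <- nrow(pts) + seq_len(nk)
    ringAng[[k + 1]] <- ang
    pts <- rbind(pts, cbind(rk * cos(ang), rk * sin(ang)))
  }
  tris <- do.call(rbind, lapply(seq_len(K), function(k)
    .annulusTris(ringIdx[[k]], ringAng[[k]], ringIdx[[k + 1]], ringAng[[k + 1]])))
  # consistent counter-clockwise orientation
  a <- .triAreas(pts, tris)
  flip <- a < 0
  if (any(flip)) tris[flip, 2:3] <- tris[flip, 3:2]
  list(points = pts, triangles = tris)
}

#' Cylinder fixture
#'
#' Tetrahedral mesh of a circular cylinder (axis along z from the origin),
#' built by extruding a concentric-ring disk triangulation into prism layers,
#' each split into three tetrahedra with globally consistent face diagonals.
#' The mesh volume equals the faceted-disk area times the length exactly, so
#' it approaches pi r^2 L as the edge length shrinks.
#'
#' @param radius,length cylinder dimensions, mm.
#' @param edge maximum element edge length, mm.
#' @param hu uniform Hounsfield value.
#' @return a \linkS4class{TetMesh} with landmarks \code{end_a_centre} and
#'   \code{end_b_centre}.
#' @export
generateCylinderFixture <- function(radius, length, edge, hu) {
  if (radius <= 0 || length <= 0 || edge <= 0)
    stop("cylinder dimensions and edge length must be positive")
  if (edge > min(radius, length))
    stop("edge length exceeds the smallest cylinder dimension")
  disk <- .diskTriangulation(radius, edge / 2)
  nz <- max(1L, as.integer(ceiling(length / (edge / 2))))
  zs <- seq(0, length, length.out = nz + 1)
  np <- nrow(disk$points)
  nodes <- cbind(disk$points[rep(seq_len(np), nz + 1), , drop = FALSE],
                 rep(zs, each = np))
  elems <- vector("list", nz)
  for (l in seq_len(nz)) {
    off <- (l - 1L) * np
    bot <- disk$triangles + off
    srt <- t(apply(bot, 1L, sort.int))
    i0 <- srt[, 1]; i1 <- srt[, 2]; i2 <- srt[, 3]
    elems[[l]] <- rbind(cbind(i0, i1, i2, i2 + np),
                        cbind(i0, i1, i1 + np, i2 + np),
                        cbind(i0, i0 + np, i1 + np, i2 + np))
  }
  elements <- do.call(rbind, elems)
  storage.mode(elements) <- "integer"
  tetMesh(nodes, elements, rep(hu, nrow(elements)),
          landmarks = list(end_a_centre = c(0, 0, 0),
                           end_b_centre = c(0, 0, length)),
          groundTruth = list(type = "cylinder", radius = radius,
                             length = length))
}
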