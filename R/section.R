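#' Triangle Gaussian quadrature rules
#'
#' Symmetric rules on the reference triangle, in barycentric coordinates with
#' weights summing to 1/2: the 3-point interior rule (barycentric
#' permutations of (2/3, 1/6, 1/6), equal weights; exact to total degree 2)
#' and the 7-point rule (centroid plus two symmetric three-point orbits;
#' exact to degree 5).
#'
#' @param n number of integration points, 3 or 7.
#' @return a \linkS4class{QuadratureRule}.
#' @examples
#' sum(gaussRule(3)@weights)   # 1/2, the reference-triangle area
#' @export
gaussRule <- function(n) {
  n <- as.integer(n)
  if (n == 3L) {
    bary <- rbind(c(2/3, 1/6, 1/6), c(1/6, 2/3, 1/6), c(1/6, 1/6, 2/3))
    w <- rep(1/6, 3)
  } else if (n == 7L) {
    a <- (6 - sqrt(15)) / 21
    b <- (6 + sqrt(15)) / 21
    wa <- (155 - sqrt(15)) / 2400
    wb <- (155 + sqrt(15)) / 2400
    bary <- rbind(c(1/3, 1/3, 1/3),
                  c(1 - 2 * a, a, a), c(a, 1 - 2 * a, a), c(a, a, 1 - 2 * a),
                  c(1 - 2 * b, b, b), c(b, 1 - 2 * b, b), c(b, b, 1 - 2 * b))
    w <- c(9/80, wa, wa, wa, wb, wb, wb)
  } else {
    stop("unsupported rule: n must be 3 or 7")
  }
  new("QuadratureRule", n = n, bary = bary, weights = w)
}

# ---- boundary extraction and polygon triangulation -------------------------

# Closed boundary contours of a plane slice: polygon edges appearing in only
# one tetrahedron lie on boundary faces of the mesh.  Vertices are identified
# by the mesh edge they sit on.  Returns a list of 2D contour matrices.
.sliceContours <- function(sl) {
  vkey <- character(0)
  vpos <- NULL
  ekeyA <- character(0)
  ekeyB <- character(0)
  for (q in seq_along(sl$polys)) {
    P <- sl$polys[[q]]
    kk <- sl$keys[[q]]
    np <- nrow(P)
    newv <- !(kk %in% vkey)
    if (any(newv)) {
      vkey <- c(vkey, kk[newv])
      vpos <- rbind(vpos, P[newv, , drop = FALSE])
    }
    j <- c(2:np, 1)
    ekeyA <- c(ekeyA, kk)
    ekeyB <- c(ekeyB, kk[j])
  }
  und <- paste(pmin(ekeyA, ekeyB), pmax(ekeyA, ekeyB))
  once <- !(duplicated(und) | duplicated(und, fromLast = TRUE))
  ea <- ekeyA[once]; eb <- ekeyB[once]
  if (!length(ea)) stop("slice has no boundary edges")
  # chain undirected boundary edges into closed cycles
  adj <- new.env(parent = emptyenv())
  addAdj <- function(a, b) {
    cur <- if (!is.null(adj[[a]])) adj[[a]] else character(0)
    assign(a, c(cur, b), envir = adj)
  }
  for (k in seq_along(ea)) { addAdj(ea[k], eb[k]); addAdj(eb[k], ea[k]) }
  visited <- new.env(parent = emptyenv())
  contours <- list()
  for (start in sort(unique(c(ea, eb)))) {
    if (!is.null(visited[[start]])) next
    path <- character(0)
    cur <- start
    prev <- ""
    repeat {
      path <- c(path, cur)
      assign(cur, TRUE, envir = visited)
      nxt <- NA_character_
      for (cand in setdiff(adj[[cur]], prev))
        if (is.null(visited[[cand]])) { nxt <- cand; break }
      if (is.na(nxt)) break
      prev <- cur
      cur <- nxt
    }
    if (length(path) >= 3)
      contours[[length(contours) + 1]] <-
        vpos[match(path, vkey), , drop = FALSE]
  }
  if (!length(contours)) stop("could not chain the slice boundary")
  contours
}

# Ear-clipping triangulation of a simple polygon (counter-clockwise or
# clockwise input; output triangles are counter-clockwise).  Robust to
# collinear vertices; falls back to clipping the widest convex corner if
# floating-point noise hides every strict ear.
.earClip <- function(P) {
  n0 <- nrow(P)
  if (.signedArea(P) < 0) P <- P[n0:1, , drop = FALSE]
  idx <- seq_len(nrow(P))
  tris <- matrix(0L, nrow(P) - 2, 3)
  t <- 0L
  eps <- 1e-12 * max(abs(P))^2
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  inTri <- function(p, a, b, c) {
    d1 <- cross2(a, b, p); d2 <- cross2(b, c, p); d3 <- cross2(c, a, p)
    d1 >= -eps && d2 >= -eps && d3 >= -eps
  }
  inTriStrict <- function(p, a, b, c) {
    cross2(a, b, p) > eps && cross2(b, c, p) > eps && cross2(c, a, p) > eps
  }
  while (length(idx) > 3) {
    m <- length(idx)
    clipped <- FALSE
    best <- NA_integer_
    bestCr <- -Inf
    for (k in seq_len(m)) {
      i0 <- idx[if (k == 1) m else k - 1]
      i1 <- idx[k]
      i2 <- idx[if (k == m) 1 else k + 1]
      cr <- cross2(P[i0, ], P[i1, ], P[i2, ])
      if (cr > bestCr) { bestCr <- cr; best <- k }
      if (cr < -eps) next                      # reflex corner, never an ear
      # convex (or collinear, zero-area) corner: an ear unless some other
      # remaining vertex lies strictly inside it
      others <- setdiff(idx, c(i0, i1, i2))
      ok <- TRUE
      for (j in others)
        if (inTriStrict(P[j, ], P[i0, ], P[i1, ], P[i2, ])) {
          ok <- FALSE; break
        }
      if (!ok) next
      t <- t + 1L
      tris[t, ] <- c(i0, i1, i2)
      idx <- idx[-k]
      clipped <- TRUE
      break
    }
    if (!clipped) {                            # numerical fallback
      k <- best
      m <- length(idx)
      i0 <- idx[if (k == 1) m else k - 1]
      i1 <- idx[k]
      i2 <- idx[if (k == m) 1 else k + 1]
      t <- t + 1L
      tris[t, ] <- c(i0, i1, i2)
      idx <- idx[-k]
    }
  }
  t <- t + 1L
  tris[t, ] <- idx
  tris <- tris[seq_len(t), , drop = FALSE]
  aSum <- sum(.triAreas(P, tris))
  aPoly <- .signedArea(P)
  if (abs(aSum - aPoly) > 1e-9 * max(abs(aPoly), 1))
    stop("ear clipping failed to partition the section polygon")
  list(vertices = P, triangles = tris)
}

.signedArea <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1)
  sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2]) / 2
}

# TRUE when segment ab properly intersects segment cd (shared endpoints are
# not counted as intersections).
.segmentsCross <- function(a, b, c, d, eps) {
  cr <- function(o, p, q)
    (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  same <- function(p, q) max(abs(p - q)) <= eps
  if (same(a, c) || same(a, d) || same(b, c) || same(b, d)) return(FALSE)
  d1 <- cr(c, d, a); d2 <- cr(c, d, b); d3 <- cr(a, b, c); d4 <- cr(a, b, d)
  (d1 > eps) != (d2 > eps) && (d3 > eps) != (d4 > eps) &&
    abs(d1) > eps && abs(d2) > eps && abs(d3) > eps && abs(d4) > eps
}

# Splice hole contours into an outer contour with bridge edges (each hole is
# connected to the outer polygon through the closest mutually visible vertex
# pair), producing a single simple polygon of area outer - sum(holes).
.spliceHoles <- function(P, holes) {
  if (.signedArea(P) < 0) P <- P[nrow(P):1, , drop = FALSE]
  scale <- max(abs(P))
  eps <- 1e-9 * scale
  for (H in holes) {
    if (.signedArea(H) > 0) H <- H[nrow(H):1, , drop = FALSE]  # holes run CW
    allEdges <- function() {
      n <- nrow(P); j <- c(2:n, 1)
      cbind(P, P[j, , drop = FALSE])
    }
    E <- allEdges()
    nh <- nrow(H)
    jh <- c(2:nh, 1)
    Eh <- cbind(H, H[jh, , drop = FALSE])
    found <- FALSE
    # candidate pairs in increasing distance
    d2 <- outer(seq_len(nh), seq_len(nrow(P)),
                function(i, j) (H[i, 1] - P[j, 1])^2 + (H[i, 2] - P[j, 2])^2)
    ord <- order(d2)
    for (k in ord) {
      i <- ((k - 1) %% nh) + 1
      j <- ((k - 1) %/% nh) + 1
      a <- H[i, ]; b <- P[j, ]
      clear <- TRUE
      for (r in seq_len(nrow(E)))
        if (.segmentsCross(a, b, E[r, 1:2], E[r, 3:4], eps)) {
          clear <- FALSE; break
        }
      if (clear) for (r in seq_len(nrow(Eh)))
        if (.segmentsCross(a, b, Eh[r, 1:2], Eh[r, 3:4], eps)) {
          clear <- FALSE; break
        }
      if (!clear) next
      cyc <- c(i:nh, seq_len(i))            # hole cycle starting/ending at i
      P <- rbind(P[seq_len(j), , drop = FALSE],
                 H[cyc, , drop = FALSE],
                 P[j:nrow(P), , drop = FALSE])
      found <- TRUE
      break
    }
    if (!found) stop("could not connect an interior void to the section boundary")
  }
  P
}

# Uniform 4-split refinement until every triangle edge is <= maxEdge.
# Children inherit the parent's containing-tet tag.
.refineTriangulation <- function(vertices, triangles, tags, maxEdge) {
  repeat {
    a <- vertices[triangles[, 1], , drop = FALSE]
    b <- vertices[triangles[, 2], , drop = FALSE]
    c <- vertices[triangles[, 3], , drop = FALSE]
    lmax <- pmax(rowSums((a - b)^2), rowSums((b - c)^2), rowSums((c - a)^2))
    long <- lmax > maxEdge^2
    if (!any(long)) break
    midKey <- new.env(parent = emptyenv())
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midKey[[key]]
      if (!is.null(hit)) return(hit)
      vertices <<- rbind(vertices, (vertices[i, ] + vertices[j, ]) / 2)
      id <- nrow(vertices)
      assign(key, id, envir = midKey)
      id
    }
    keepT <- triangles[!long, , drop = FALSE]
    keepTag <- tags[!long]
    splitT <- triangles[long, , drop = FALSE]
    splitTag <- tags[long]
    newT <- matrix(0L, 4 * nrow(splitT), 3)
    newTag <- rep(splitTag, each = 4)
    for (r in seq_len(nrow(splitT))) {
      v1 <- splitT[r, 1]; v2 <- splitT[r, 2]; v3 <- splitT[r, 3]
      m12 <- midpoint(v1, v2); m23 <- midpoint(v2, v3); m31 <- midpoint(v3, v1)
      newT[4 * r - 3, ] <- c(v1, m12, m31)
      newT[4 * r - 2, ] <- c(m12, v2, m23)
      newT[4 * r - 1, ] <- c(m31, m23, v3)
      newT[4 * r, ] <- c(m12, m23, m31)
    }
    triangles <- rbind(keepT, newT)
    tags <- c(keepTag, newTag)
  }
  list(vertices = vertices, triangles = triangles, tags = tags)
}

# ---- point-in-tetrahedron lookup -------------------------------------------

# Assign each 3D point the candidate tetrahedron with the largest minimum
# barycentric coordinate (the containing tet when one exists, the nearest
# candidate otherwise; ties broken deterministically towards the lowest
# candidate index).
.locateInTets <- function(points, mesh, candidates, tol = -1e-9) {
  P <- matrix(points, ncol = 3)
  npts <- nrow(P)
  best <- rep(-Inf, npts)
  pick <- integer(npts)
  el <- mesh@elements
  for (c in candidates) {
    en <- el[c, ]
    p1 <- mesh@nodes[en[1], ]
    M <- rbind(mesh@nodes[en[2], ] - p1, mesh@nodes[en[3], ] - p1,
               mesh@nodes[en[4], ] - p1)
    L <- sweep(P, 2, p1) %*% solve(M)       # barycentric 2..4
    minb <- pmin(1 - rowSums(L), L[, 1], L[, 2], L[, 3])
    better <- minb > best
    best[better] <- minb[better]
    pick[better] <- c
  }
  if (any(best < tol))
    stop(sprintf("integration point (%.3f, %.3f, %.3f) lies outside every candidate tetrahedron",
                 P[which.min(best), 1], P[which.min(best), 2],
                 P[which.min(best), 3]))
  pick
}

# ---- section triangulation -------------------------------------------------

#' Triangulate a cross-section
#'
#' Builds a 2D triangulation of the polygonal intersection of a cutting
#' plane with the mesh, with maximum triangle edge length \code{maxEdge}.
#' Two constructions are available:
#' \describe{
#'   \item{\code{align = "boundary"}}{(default) the exact slice boundary
#'     contour is extracted, ear-clipped and uniformly refined.  Triangles
#'     are independent of the interior tetrahedral structure, so integration
#'     points of one triangle may fall in different tetrahedra - the
#'     realistic regime for quadrature-order comparisons.}
#'   \item{\code{align = "tets"}}{each per-tetrahedron slice polygon is fan
#'     triangulated and refined, so every triangle lies inside a single
#'     tetrahedron and quadrature of the piecewise-constant energy density is
#'     exact at any order.}
#' }
#' In both cases the triangle areas sum to the section area and each triangle
#' carries the tetrahedron containing its centroid.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param plane a \linkS4class{SectionPlane} (or any object with origin and
#'   normal set via \code{sectionPlane()}).
#' @param maxEdge maximum triangle edge, mm (default 5, the converged section
#'   mesh size).
#' @param align \code{"boundary"} or \code{"tets"}.
#' @return a \linkS4class{SectionTriangulation}.
#' @export
triangulateSection <- function(mesh, plane, maxEdge = 5,
                               align = c("boundary", "tets")) {
  align <- match.arg(align)
  sl <- .slicePlane(mesh, plane@origin, plane@normal)
  if (is.null(sl)) stop("plane does not intersect the mesh")
  area <- sum(vapply(sl$polys, .polyArea, numeric(1)))

  if (align == "tets") {
    verts <- NULL
    tris <- NULL
    tags <- integer(0)
    for (q in seq_along(sl$polys)) {
      P <- sl$polys[[q]]
      off <- if (is.null(verts)) 0L else nrow(verts)
      verts <- rbind(verts, P)
      np <- nrow(P)
      fan <- cbind(rep(off + 1L, np - 2), off + 2:(np - 1), off + 3:np)
      tris <- rbind(tris, fan)
      tags <- c(tags, rep(sl$tetIds[q], np - 2))
    }
  } else {
    contours <- .sliceContours(sl)
    absA <- vapply(contours, function(P) abs(.signedArea(P)), numeric(1))
    # nesting depth of each contour (odd depth = hole)
    nC <- length(contours)
    depth <- integer(nC)
    parent <- rep(NA_integer_, nC)
    for (i in seq_len(nC)) {
      ci <- .polyCentroid2(contours[[i]])
      enclosing <- Inf
      for (j in seq_len(nC)) {
        if (i == j || absA[j] <= absA[i]) next
        if (.pointInPoly(ci, contours[[j]])) {
          depth[i] <- depth[i] + 1L
          if (absA[j] < enclosing) { enclosing <- absA[j]; parent[i] <- j }
        }
      }
    }
    outers <- which(depth %% 2L == 0L)
    verts <- NULL
    tris <- NULL
    for (oi in outers) {
      holes <- contours[which(parent == oi & depth %% 2L == 1L)]
      P <- if (length(holes)) .spliceHoles(contours[[oi]], holes)
           else contours[[oi]]
      ec <- .earClip(P)
      off <- if (is.null(verts)) 0L else nrow(verts)
      verts <- rbind(verts, ec$vertices)
      tris <- rbind(tris, ec$triangles + off)
    }
    tags <- rep(NA_integer_, nrow(tris))
  }
  # orient counter-clockwise, then refine
  a2 <- .triAreas(verts, tris)
  flip <- a2 < 0
  if (any(flip)) tris[flip, 2:3] <- tris[flip, 3:2]
  keep <- abs(a2) > 1e-12 * max(area, 1)
  tris <- tris[keep, , drop = FALSE]
  tags <- tags[keep]
  rf <- .refineTriangulation(verts, tris, tags, maxEdge)

  centroids2 <- (rf$vertices[rf$triangles[, 1], , drop = FALSE] +
                 rf$vertices[rf$triangles[, 2], , drop = FALSE] +
                 rf$vertices[rf$triangles[, 3], , drop = FALSE]) / 3
  centroids3 <- sweep(centroids2 %*% t(sl$basis), 2, sl$origin, `+`)
  triTet <- rf$tags
  missing <- which(is.na(triTet))
  if (length(missing))
    triTet[missing] <- .locateInTets(centroids3[missing, , drop = FALSE],
                                     mesh, sl$tetIds)
  plane@origin <- as.vector(sl$origin)   # keep the 2D frame consistent
  plane@area <- area
  new("SectionTriangulation", plane = plane, basis = sl$basis,
      vertices = rf$vertices, triangles = rf$triangles,
      triTet = as.integer(triTet), candidateTets = as.integer(sl$tetIds),
      align = align)
}

.pointInPoly <- function(p, P) {
  n <- nrow(P)
  j <- c(2:n, 1)
  crossings <- 0L
  for (k in seq_len(n)) {
    a <- P[k, ]; b <- P[j[k], ]
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
      if (xint > p[1]) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

#' Construct a section plane
#'
#' @param origin point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @param label section label.
#' @param area optional precomputed intersection area (mm^2).
#' @return a \linkS4class{SectionPlane}.
#' @export
sectionPlane <- function(origin, normal, label = "custom", area = 0) {
  new("SectionPlane", origin = as.numeric(origin),
      normal = .unit(as.numeric(normal)), label = label, area = area)
}

# Integrate a per-tetrahedron-constant density over the triangulation:
# sum_e sum_i W_i |J_e| density(tet containing x_i).
.sectionIntegrate <- function(tri, rule, densityPerTet, mesh) {
  m <- nrow(tri@triangles)
  A <- .triAreas(tri@vertices, tri@triangles)
  J <- 2 * A
  perTri <- numeric(m)
  v1 <- tri@vertices[tri@triangles[, 1], , drop = FALSE]
  v2 <- tri@vertices[tri@triangles[, 2], , drop = FALSE]
  v3 <- tri@vertices[tri@triangles[, 3], , drop = FALSE]
  for (i in seq_len(rule@n)) {
    bc <- rule@bary[i, ]
    p2 <- bc[1] * v1 + bc[2] * v2 + bc[3] * v3
    if (tri@align == "tets") {
      tets <- tri@triTet
    } else {
      p3 <- sweep(p2 %*% t(tri@basis), 2,
                  .sliceOrigin(tri), `+`)
      tets <- .locateInTets(p3, mesh, tri@candidateTets)
    }
    perTri <- perTri + rule@weights[i] * J * densityPerTet[tets]
  }
  list(total = sum(perTri), perTriangle = perTri)
}

# The 2D frame origin used by a triangulation: the plane origin expressed in
# its own basis maps 2D (0,0) to the (possibly nudged) slicing origin, which
# is recovered from the stored plane and basis.
.sliceOrigin <- function(tri) tri@plane@origin

#' Cross-section strain energy
#'
#' Load-induced strain energy of a cross-section: the strain-energy density
#' of the finite element solution (constant within each linear tetrahedron)
#' integrated over the section triangulation by Gaussian quadrature,
#' \eqn{U = \sum_e \sum_i W_i |J_e| \hat U_i}.  Units: energy per unit
#' thickness, N.mm/mm.
#'
#' @param solution an \linkS4class{FESolution} on the same mesh.
#' @param mesh the \linkS4class{TetMesh} the triangulation was built from.
#' @param tri a \linkS4class{SectionTriangulation}.
#' @param rule a \linkS4class{QuadratureRule} (default 3-point).
#' @return the scalar energy U.
#' @export
sectionStrainEnergy <- function(solution, mesh, tri, rule = gaussRule(3)) {
  .sectionIntegrate(tri, rule, solution@energyDensity, mesh)$total
}

#' Cross-section yield strain energy
#'
#' Maximum allowable (yield) strain energy of a cross-section: the yield
#' energy density \eqn{\sigma_Y^2 / (2E)} of each material point (a function
#' of bone density only) integrated over the triangulation by Gaussian
#' quadrature.  Independent of the load case.
#'
#' @param materials a \linkS4class{MaterialTable} for the mesh.
#' @inheritParams sectionStrainEnergy
#' @return the scalar energy U_Y.
#' @export
sectionYieldEnergy <- function(materials, mesh, tri, rule = gaussRule(3)) {
  dens <- yieldEnergyDensity(elementE(materials),
                             elementYieldStress(materials))
  .sectionIntegrate(tri, rule, dens, mesh)$total
}

#' Fracture risk index
#'
#' \eqn{\eta = U / U_Y}: the ratio of the load-induced to the yield strain
#' energy of a cross-section.  \eqn{\eta > 1} indicates possible fracture.
#'
#' @param U load-induced section strain energy.
#' @param UY yield section strain energy; must be positive.
#' @return dimensionless index.
#' @export
fractureRiskIndex <- function(U, UY) {
  if (any(UY <= 0)) stop("U_Y must be positive")
  U / UY
}

#' Section maxima of the von Mises fields
#'
#' Maximum per-element von Mises stress and equivalent strain over the set
#' of tetrahedra intersected by the section plane.
#'
#' @param solution an \linkS4class{FESolution}.
#' @param tri a \linkS4class{SectionTriangulation}.
#' @return named numeric vector \code{c(stress = , strain = )}.
#' @export
sectionFieldMaxima <- function(solution, tri) {
  tets <- unique(c(tri@candidateTets, tri@triTet))
  if (!length(tets)) stop("empty section element set")
  c(stress = max(solution@vmStress[tets]),
    strain = max(solution@vmStrain[tets]))
}

#' Full strain-energy evaluation of one section
#'
#' Convenience wrapper computing U, U_Y, the fracture risk index and the von
#' Mises field maxima for one triangulated cross-section.
#'
#' @inheritParams sectionStrainEnergy
#' @param materials a \linkS4class{MaterialTable}.
#' @return a \linkS4class{SectionEnergyResult}.
#' @export
sectionEnergy <- function(solution, materials, mesh, tri,
                          rule = gaussRule(3)) {
  su <- .sectionIntegrate(tri, rule, solution@energyDensity, mesh)
  dens <- yieldEnergyDensity(elementE(materials),
                             elementYieldStress(materials))
  sy <- .sectionIntegrate(tri, rule, dens, mesh)
  mx <- sectionFieldMaxima(solution, tri)
  new("SectionEnergyResult", label = tri@plane@label,
      area = tri@plane@area, U = su$total, UY = sy$total,
      eta = fractureRiskIndex(su$total, sy$total),
      perTriangleU = su$perTriangle, perTriangleUY = sy$perTriangle,
      ruleN = rule@n, maxVmStress = unname(mx["stress"]),
      maxVmStrain = unname(mx["strain"]))
}

#' @rdname SectionEnergyResult-accessors
#' @export
setMethod("fri", "SectionEnergyResult", function(x) x@eta)

#' SectionEnergyResult accessors
#'
#' @param x a \linkS4class{SectionEnergyResult}.
#' @return \code{fri}: the fracture risk index eta.
#' @name SectionEnergyResult-accessors
NULL

setMethod("show", "SectionEnergyResult", function(object) {
  cat(sprintf("Section '%s' (area %.1f mm^2, %d-point rule):\n",
              object@label, object@area, object@ruleN))
  cat(sprintf("  U = %.4g, U_Y = %.4g N.mm/mm, eta = %.4g\n",
              object@U, object@UY, object@eta))
  cat(sprintf("  max von Mises stress %.4g MPa, strain %.4g\n",
              object@maxVmStress, object@maxVmStrain))
})
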