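# Internal geometry helpers shared across modules.

.norm3 <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .norm3(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# Signed volumes of tetrahedra, vectorized: det([p2-p1 p3-p1 p4-p1]) / 6.
.tetVolumes <- function(nodes, elements) {
  p1 <- nodes[elements[, 1], , drop = FALSE]
  a <- nodes[elements[, 2], , drop = FALSE] - p1
  b <- nodes[elements[, 3], , drop = FALSE] - p1
  c <- nodes[elements[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
   a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# Reorder tetrahedra in place so every signed volume is positive.
.orientTets <- function(nodes, elements) {
  v <- .tetVolumes(nodes, elements)
  flip <- which(v < 0)
  if (length(flip)) {
    tmp <- elements[flip, 3]
    elements[flip, 3] <- elements[flip, 4]
    elements[flip, 4] <- tmp
  }
  elements
}

.tetCentroids <- function(nodes, elements) {
  (nodes[elements[, 1], , drop = FALSE] + nodes[elements[, 2], , drop = FALSE] +
   nodes[elements[, 3], , drop = FALSE] + nodes[elements[, 4], , drop = FALSE]) / 4
}

# Signed areas (positive for counter-clockwise triangles) in 2D.
.triAreas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c <- vertices[triangles[, 3], , drop = FALSE]
  ((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
   (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])) / 2
}

# Deterministic orthonormal in-plane basis (u, v) with u x v = normal.
.planeBasis <- function(normal) {
  n <- .unit(normal)
  ref <- c(0, 0, 0)
  ref[which.min(abs(n))] <- 1
  u <- .unit(.cross3(ref, n))
  v <- .cross3(n, u)
  cbind(u, v)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Boundary faces of a tet mesh: faces that belong to exactly one element.
# Returns a list with the face matrix (rows of node triples) and the owning
# element of each boundary face.
.boundaryFaces <- function(elements) {
  m <- nrow(elements)
  idx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- matrix(0L, 4L * m, 3L)
  owner <- rep(seq_len(m), each = 4L)
  for (k in 1:4) faces[seq(k, by = 4L, length.out = m), ] <- elements[, idx[k, ]]
  sorted <- t(apply(faces, 1L, sort.int))
  key <- paste(sorted[, 1], sorted[, 2], sorted[, 3])
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  list(faces = faces[once, , drop = FALSE], owner = owner[once])
}

.surfaceNodes <- function(mesh) {
  sort(unique(as.vector(.boundaryFaces(mesh@elements)$faces)))
}

# Union-find over node labels; returns the element subset forming the largest
# connected component (by summed volume).
.largestComponent <- function(nodes, elements) {
  n <- nrow(nodes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(elements))) {
    r <- find(elements[e, 1])
    for (k in 2:4) {
      s <- find(elements[e, k])
      if (s != r) parent[s] <- r
    }
  }
  comp <- vapply(elements[, 1], find, integer(1))
  vols <- .tetVolumes(nodes, elements)
  keep <- comp == names(which.max(tapply(vols, comp, sum)))
  which(keep)
}

# Drop unused nodes, renumber elements; preserves element order.
.compactMesh <- function(nodes, elements) {
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  list(nodes = nodes[used, , drop = FALSE],
       elements = matrix(remap[elements], ncol = 4))
}
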