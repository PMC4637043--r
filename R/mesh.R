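#' Construct a TetMesh
#'
#' Assembles a \linkS4class{TetMesh} from node coordinates, tetrahedra and a
#' per-element HU field.  Tetrahedra are reoriented so that every signed
#' volume is positive.
#'
#' @param nodes numeric n x 3 matrix of coordinates (mm).
#' @param elements m x 4 matrix of 1-based node indices.
#' @param hu numeric vector of Hounsfield units, one per element.
#' @param landmarks named list of 3-vectors.
#' @param groundTruth optional list of construction ground truth.
#' @return a validated \linkS4class{TetMesh}.
#' @export
tetMesh <- function(nodes, elements, hu, landmarks = list(),
                    groundTruth = list()) {
  nodes <- as.matrix(nodes)
  dimnames(nodes) <- NULL
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  dimnames(elements) <- NULL
  storage.mode(elements) <- "integer"
  elements <- .orientTets(nodes, elements)
  new("TetMesh", nodes = nodes, elements = elements, hu = as.numeric(hu),
      landmarks = landmarks, groundTruth = groundTruth)
}

#' TetMesh accessors
#'
#' @param x a \linkS4class{TetMesh}.
#' @return \code{nodes}: n x 3 coordinate matrix (mm); \code{elements}:
#'   m x 4 index matrix; \code{elementHU}: HU per element;
#'   \code{landmarks}/\code{groundTruth}: named lists; \code{nNodes},
#'   \code{nElements}: counts; \code{tetVolumes}: signed element volumes
#'   (mm^3, all positive).
#' @name TetMesh-accessors
NULL

#' @rdname TetMesh-accessors
#' @export
setMethod("nodes", "TetMesh", function(x) x@nodes)
#' @rdname TetMesh-accessors
#' @export
setMethod("elements", "TetMesh", function(x) x@elements)
#' @rdname TetMesh-accessors
#' @export
setMethod("elementHU", "TetMesh", function(x) x@hu)
#' @rdname TetMesh-accessors
#' @export
setMethod("landmarks", "TetMesh", function(x) x@landmarks)
#' @rdname TetMesh-accessors
#' @export
setMethod("groundTruth", "TetMesh", function(x) x@groundTruth)
#' @rdname TetMesh-accessors
#' @export
setMethod("nNodes", "TetMesh", function(x) nrow(x@nodes))
#' @rdname TetMesh-accessors
#' @export
setMethod("nElements", "TetMesh", function(x) nrow(x@elements))
#' @rdname TetMesh-accessors
#' @export
setMethod("tetVolumes", "TetMesh", function(x) .tetVolumes(x@nodes, x@elements))

#' Surface nodes of a tetrahedral mesh
#'
#' Nodes lying on boundary faces (faces owned by exactly one tetrahedron).
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @return sorted integer vector of node indices.
#' @export
surfaceNodes <- function(mesh) .surfaceNodes(mesh)

setMethod("show", "TetMesh", function(object) {
  cat("TetMesh:", nrow(object@nodes), "nodes,", nrow(object@elements),
      "tetrahedra\n")
  v <- .tetVolumes(object@nodes, object@elements)
  cat(sprintf("  volume %.1f mm^3, HU range [%.0f, %.0f]\n",
              sum(v), min(object@hu), max(object@hu)))
  if (length(object@landmarks))
    cat("  landmarks:", paste(names(object@landmarks), collapse = ", "), "\n")
  if (length(object@groundTruth))
    cat("  ground truth: neck-shaft angle",
        object@groundTruth$neck_shaft_angle, "deg\n")
})
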