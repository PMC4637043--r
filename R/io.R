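# Mesh import/export: legacy ASCII VTK unstructured grids (element HU as
# CELL_DATA, landmarks and ground truth as FIELD metadata) and a CSV
# node/element table dialect.

#' Write a mesh as legacy ASCII VTK
#'
#' Unstructured-grid legacy VTK with the tetrahedra as cell type 10, the
#' per-element HU field as cell data and the landmarks / numeric ground
#' truth entries as named FIELD arrays.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMeshVTK <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh@nodes); m <- nrow(mesh@elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "femfri tetrahedral mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(format(mesh@nodes, digits = 17, trim = TRUE,
                          scientific = TRUE), 1, paste, collapse = " "), con)
  writeLines(paste("CELLS", m, 5 * m), con)
  writeLines(apply(cbind(4L, mesh@elements - 1L), 1, paste, collapse = " "),
             con)
  writeLines(paste("CELL_TYPES", m), con)
  writeLines(rep("10", m), con)
  writeLines(c(paste("CELL_DATA", m), "SCALARS hu double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(mesh@hu, digits = 17, trim = TRUE, scientific = TRUE),
             con)
  meta <- c(lapply(mesh@landmarks, as.numeric),
            Filter(is.numeric, mesh@groundTruth))
  names(meta) <- c(paste0("landmark_", names(mesh@landmarks)),
                   paste0("truth_", names(Filter(is.numeric,
                                                 mesh@groundTruth))))
  if (length(meta)) {
    writeLines(paste("FIELD femfri_metadata", length(meta)), con)
    for (nm in names(meta)) {
      v <- meta[[nm]]
      writeLines(paste(nm, length(v), 1, "double"), con)
      writeLines(paste(format(v, digits = 17, trim = TRUE,
                              scientific = TRUE), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK tetrahedral mesh
#'
#' Reads unstructured-grid legacy VTK files with tetrahedral cells.  A
#' \code{hu} cell-data scalar array, \code{landmark_*} and \code{truth_*}
#' FIELD arrays written by \code{\link{writeMeshVTK}} are restored when
#' present; meshes from other tools load with zero HU and no landmarks.
#'
#' @param path VTK file.
#' @return a \linkS4class{TetMesh}.
#' @export
readMeshVTK <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(toks(lines[ip])[2])
  pts <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = " "),
              n = 3 * n, quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  m <- as.integer(toks(lines[ic])[2])
  cells <- scan(text = paste(lines[(ic + 1):(ic + m)], collapse = " "),
                n = 5 * m, quiet = TRUE)
  cells <- matrix(as.integer(cells), ncol = 5, byrow = TRUE)
  if (any(cells[, 1] != 4L)) stop("only tetrahedral (4-node) cells are supported")
  elementsM <- cells[, 2:5] + 1L
  hu <- rep(0, m)
  ih <- grep("^SCALARS hu", lines)
  if (length(ih)) {
    hu <- scan(text = paste(lines[(ih[1] + 2):length(lines)], collapse = " "),
               n = m, quiet = TRUE)
  }
  landmarksL <- list()
  truthL <- list()
  fi <- grep("^FIELD", lines)
  if (length(fi)) {
    k <- fi[1] + 1L
    nArrays <- as.integer(toks(lines[fi[1]])[3])
    for (a in seq_len(nArrays)) {
      hdr <- toks(lines[k])
      len <- as.integer(hdr[2])
      v <- scan(text = paste(lines[(k + 1):length(lines)], collapse = " "),
                n = len, quiet = TRUE)
      nm <- hdr[1]
      if (startsWith(nm, "landmark_"))
        landmarksL[[sub("^landmark_", "", nm)]] <- v
      else if (startsWith(nm, "truth_"))
        truthL[[sub("^truth_", "", nm)]] <- if (len == 1) v else v
      k <- k + 1L + ceiling(len / max(len, 1))
    }
  }
  tetMesh(nodes, elementsM, hu, landmarksL, truthL)
}

#' Write / read a mesh as CSV tables
#'
#' Fallback plain-table dialect: \code{<stem>_nodes.csv} (x, y, z),
#' \code{<stem>_elements.csv} (n1..n4, hu) and, when present,
#' \code{<stem>_landmarks.csv} (name, x, y, z).
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param stem path stem for the three files.
#' @return \code{writeMeshCSV}: the stem, invisibly; \code{readMeshCSV}: a
#'   \linkS4class{TetMesh} (without ground truth).
#' @export
writeMeshCSV <- function(mesh, stem) {
  nd <- as.data.frame(mesh@nodes)
  names(nd) <- c("x", "y", "z")
  write.csv(nd, paste0(stem, "_nodes.csv"), row.names = FALSE)
  el <- as.data.frame(mesh@elements)
  names(el) <- paste0("n", 1:4)
  el$hu <- mesh@hu
  write.csv(el, paste0(stem, "_elements.csv"), row.names = FALSE)
  if (length(mesh@landmarks)) {
    lm <- do.call(rbind, mesh@landmarks)
    write.csv(data.frame(name = names(mesh@landmarks), x = lm[, 1],
                         y = lm[, 2], z = lm[, 3]),
              paste0(stem, "_landmarks.csv"), row.names = FALSE)
  }
  invisible(stem)
}

#' @rdname writeMeshCSV
#' @export
readMeshCSV <- function(stem) {
  nd <- read.csv(paste0(stem, "_nodes.csv"))
  el <- read.csv(paste0(stem, "_elements.csv"))
  lmPath <- paste0(stem, "_landmarks.csv")
  landmarksL <- list()
  if (file.exists(lmPath)) {
    lm <- read.csv(lmPath)
    landmarksL <- lapply(seq_len(nrow(lm)),
                         function(i) as.numeric(lm[i, c("x", "y", "z")]))
    names(landmarksL) <- lm$name
  }
  tetMesh(as.matrix(nd), as.matrix(el[, paste0("n", 1:4)]), el$hu,
          landmarksL)
}

#' Write a finite element solution as legacy ASCII VTK
#'
#' The mesh with nodal displacement vectors as point data and the element
#' fields (HU, strain-energy density, von Mises stress and strain, Voigt
#' stress components) as cell data, for inspection in ParaView-like viewers.
#'
#' @param mesh the \linkS4class{TetMesh} that was solved.
#' @param solution an \linkS4class{FESolution}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSolutionVTK <- function(mesh, solution, path) {
  writeMeshVTK(mesh, path)
  con <- file(path, "a")
  on.exit(close(con))
  n <- nrow(mesh@nodes)
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)
  writeLines(c(paste("POINT_DATA", n), "VECTORS displacement double"), con)
  writeLines(apply(fmt(solution@displacements), 1, paste, collapse = " "),
             con)
  scalars <- list(energy_density = solution@energyDensity,
                  von_mises_stress = solution@vmStress,
                  von_mises_strain = solution@vmStrain)
  for (nm in names(scalars)) {
    writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"),
               con)
    writeLines(fmt(scalars[[nm]]), con)
  }
  writeLines("TENSORS stress double", con)
  s <- solution@stress
  full <- cbind(s[, 1], s[, 4], s[, 6], s[, 4], s[, 2], s[, 5],
                s[, 6], s[, 5], s[, 3])
  writeLines(apply(fmt(full), 1, paste, collapse = " "), con)
  invisible(path)
}
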