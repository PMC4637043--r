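# End-to-end pipeline driver and the convergence-study utilities.

#' Create a run configuration
#'
#' Assembles and validates the configuration driving
#' \code{\link{runPipeline}}.  Either a phantom specification or a mesh path
#' (VTK, or a CSV table stem) identifies the input geometry.  Defaults mirror
#' the converged analysis settings: 8 mm femur mesh edge, 50 material bins,
#' 5 mm section mesh edge, 3-point quadrature.
#'
#' @param phantom a \linkS4class{PhantomSpec} (default: the standard
#'   phantom), or \code{NULL} when \code{meshPath} is given.
#' @param meshPath optional path to a VTK mesh (or CSV stem).
#' @param bodyWeightN subject body weight, N.
#' @param heightCm subject height, cm.
#' @param configurations subset of \code{c("stance", "fall")}.
#' @param nBins number of material bins.
#' @param nu Poisson ratio.
#' @param quadratureN 3 or 7 integration points.
#' @param sectionMaxEdge section triangle edge bound, mm.
#' @param headCapture,trochCapture,distalTol load-case capture radii (see
#'   \code{\link{buildLoadCase}}).
#' @param seed integer seed (forwarded to the phantom generator).
#' @param outputDir optional directory for reports and solution exports.
#' @return a validated \code{femfri_config} list.
#' @export
runConfig <- function(phantom = phantomSpec(), meshPath = NULL,
                      bodyWeightN = 700, heightCm = 170,
                      configurations = c("stance", "fall"),
                      nBins = 50L, nu = 0.4, quadratureN = 3L,
                      sectionMaxEdge = 5, headCapture = 1.05,
                      trochCapture = 12, distalTol = 5,
                      seed = 1L, outputDir = NULL) {
  configurations <- match.arg(configurations, c("stance", "fall"),
                              several.ok = TRUE)
  stopifnot(bodyWeightN > 0, heightCm > 0, nBins >= 1, nu > 0, nu < 0.5,
            quadratureN %in% c(3L, 7L), sectionMaxEdge > 0,
            headCapture > 0, trochCapture > 0, distalTol > 0)
  if (!is.null(phantom) && !is.null(meshPath))
    stop("give either a phantom spec or a mesh path, not both")
  if (is.null(phantom) && is.null(meshPath))
    stop("one of phantom or meshPath is required")
  if (!is.null(phantom)) {
    phantom@seed <- as.integer(seed)
    validObject(phantom)
  }
  structure(list(phantom = phantom, meshPath = meshPath,
                 bodyWeightN = bodyWeightN, heightCm = heightCm,
                 configurations = configurations, nBins = as.integer(nBins),
                 nu = nu, quadratureN = as.integer(quadratureN),
                 sectionMaxEdge = sectionMaxEdge,
                 headCapture = headCapture, trochCapture = trochCapture,
                 distalTol = distalTol, seed = as.integer(seed),
                 outputDir = outputDir),
            class = "femfri_config")
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the \code{\link{runConfig}} arguments; a nested
#' \code{phantom:} mapping (keys = \linkS4class{PhantomSpec} slots) overrides
#' the standard phantom.
#'
#' @param path YAML file.
#' @return a \code{femfri_config}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), "phantom")]
  if (!is.null(y$phantom))
    args$phantom <- do.call(phantomSpec, y$phantom)
  do.call(runConfig, args)
}

#' Run the full fracture-risk pipeline
#'
#' Executes phantom generation (or mesh import), material binning, femoral
#' axis identification, the finite element solves for the requested load
#' configurations, and the strain-energy evaluation of the three critical
#' cross-sections.  Returns (and optionally writes) a run report with the
#' applied forces, the recovered anatomy, and per-section U, U_Y, the
#' fracture risk index eta and the von Mises field maxima.
#'
#' @param config a \code{femfri_config} from \code{\link{runConfig}}.
#' @param keepObjects if \code{TRUE}, attach the mesh, materials, solutions
#'   and triangulations to the result (for programmatic reuse).
#' @return a list with elements \code{report} (plain-data summary, also
#'   serialized to JSON/CSV when \code{outputDir} is set) and, when
#'   requested, \code{objects}.
#' @export
runPipeline <- function(config, keepObjects = FALSE) {
  stopifnot(inherits(config, "femfri_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  mesh <- stage("geometry", {
    if (!is.null(config$phantom)) generatePhantom(config$phantom)
    else if (grepl("\\.vtk$", config$meshPath)) readMeshVTK(config$meshPath)
    else readMeshCSV(config$meshPath)
  })
  materials <- stage("materials",
                     binMaterials(mesh, nBins = config$nBins, nu = config$nu))
  axes <- stage("anatomy", femoralAxes(mesh))
  sections <- stage("anatomy", findCriticalSections(mesh, axes))
  tris <- stage("section_mesh", lapply(sections, function(pl)
    triangulateSection(mesh, pl, maxEdge = config$sectionMaxEdge)))
  rule <- gaussRule(config$quadratureN)

  solutions <- list()
  sectionRows <- list()
  forces <- list()
  for (cfg in config$configurations) {
    load <- stage(paste0("load_", cfg),
                  buildLoadCase(mesh, cfg, w = config$bodyWeightN,
                                h = config$heightCm, axes = axes,
                                headCapture = config$headCapture,
                                trochCapture = config$trochCapture,
                                distalTol = config$distalTol))
    sol <- stage(paste0("fea_", cfg), solveFE(mesh, materials, load))
    solutions[[cfg]] <- sol
    forces[[cfg]] <- load@totalForce
    for (lbl in names(tris)) {
      se <- stage("section_energy",
                  sectionEnergy(sol, materials, mesh, tris[[lbl]], rule))
      sectionRows[[length(sectionRows) + 1]] <- data.frame(
        configuration = cfg, section = lbl, area_mm2 = se@area,
        U = se@U, U_Y = se@UY, eta = se@eta,
        max_von_mises_stress_MPa = se@maxVmStress,
        max_von_mises_strain = se@maxVmStrain)
    }
  }
  sectionTable <- do.call(rbind, sectionRows)

  report <- list(
    package_version = as.character(utils::packageVersion("femfri")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    constants = list(stance_factor = 2.5, impact_factor = 8.25,
                     density_intercept = 0.04162, density_slope = 0.000854,
                     modulus_coef = 10500, modulus_exp = 2.29,
                     yield_coef = 116, yield_exp = 2.03,
                     poisson = config$nu),
    subject = list(body_weight_N = config$bodyWeightN,
                   height_cm = config$heightCm),
    applied_forces_N = forces,
    mesh = list(n_nodes = nNodes(mesh), n_elements = nElements(mesh)),
    anatomy = list(neck_shaft_angle_deg = axes@angle,
                   head_centre = axes@headCentre,
                   head_radius_mm = axes@headRadius),
    quadrature_points = config$quadratureN,
    section_max_edge_mm = config$sectionMaxEdge,
    sections = sectionTable,
    elapsed_s = proc.time()[["elapsed"]] - t0)

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(sectionTable, file.path(config$outputDir, "sections.csv"),
              row.names = FALSE)
    writeMeshVTK(mesh, file.path(config$outputDir, "mesh.vtk"))
    writeMaterialCSV(materials,
                     file.path(config$outputDir, "materials.csv"))
    for (cfg in names(solutions))
      writeSolutionVTK(mesh, solutions[[cfg]],
                       file.path(config$outputDir,
                                 paste0("solution_", cfg, ".vtk")))
  }
  out <- list(report = report)
  if (keepObjects)
    out$objects <- list(mesh = mesh, materials = materials, axes = axes,
                        sections = sections, triangulations = tris,
                        solutions = solutions)
  out
}

#' Convergence study over one analysis knob
#'
#' Reruns the pipeline varying a single discretization parameter and
#' tabulates the monitored quantities: the mean displacement magnitude of
#' the loaded nodes (first configuration) and the fracture risk index at the
#' smallest-neck section, together with successive relative changes.
#'
#' @param config a \code{femfri_config} (phantom input required for
#'   \code{mesh_edge}).
#' @param variable one of \code{"mesh_edge"}, \code{"n_bins"},
#'   \code{"section_edge"}, \code{"quadrature_n"}.
#' @param values at least two parameter values.
#' @return data.frame with the value, monitored displacement (mm), eta at
#'   the smallest neck, and successive relative changes of each.
#' @export
convergenceStudy <- function(config,
                             variable = c("mesh_edge", "n_bins",
                                          "section_edge", "quadrature_n"),
                             values) {
  variable <- match.arg(variable)
  if (length(values) < 2) stop("at least two values are required")
  rows <- lapply(values, function(v) {
    cfg <- config
    if (variable == "mesh_edge") {
      if (is.null(cfg$phantom))
        stop("mesh_edge studies need a phantom input")
      cfg$phantom@targetEdgeLength <- v
    } else if (variable == "n_bins") {
      cfg$nBins <- as.integer(v)
    } else if (variable == "section_edge") {
      cfg$sectionMaxEdge <- v
    } else {
      cfg$quadratureN <- as.integer(v)
    }
    res <- runPipeline(cfg, keepObjects = TRUE)
    sol <- res$objects$solutions[[config$configurations[1]]]
    u <- displacements(sol)[sol@load@loadedNodes, , drop = FALSE]
    monitored <- mean(sqrt(rowSums(u^2)))
    st <- res$report$sections
    eta <- st$eta[st$section == "smallest_neck" &
                  st$configuration == config$configurations[1]]
    data.frame(value = v, monitored_displacement_mm = monitored,
               eta_smallest_neck = eta)
  })
  tab <- do.call(rbind, rows)
  relchg <- function(x) c(NA, abs(diff(x)) / abs(x[-length(x)]))
  tab$rel_change_displacement <- relchg(tab$monitored_displacement_mm)
  tab$rel_change_eta <- relchg(tab$eta_smallest_neck)
  tab
}
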