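#' @import methods
#' @importFrom stats rnorm prcomp quantile
#' @importFrom utils head tail write.csv read.csv
NULL

#' Synthetic proximal-femur phantom specification
#'
#' Geometric and imaging parameters of the synthetic femur phantom: a distal
#' shaft cylinder, an angled neck cylinder (optionally waisted so a smallest
#' neck cross-section exists in the interior of the neck) and a spherical head,
#' wrapped in a cortical shell of uniform thickness.  All lengths are in mm,
#' intensities in Hounsfield units (HU).
#'
#' Defaults describe a generic adult proximal femur: 100 mm shaft segment of
#' radius 14 mm, 50 mm neck of radius 15 mm with a 2 mm deep isthmus, 24 mm
#' head and a 130 degree neck-shaft angle.  The cortical shell (1200 HU) lies
#' within the usual cortical segmentation window of 200-2000 HU and the
#' cancellous interior (150 HU) within 100-200 HU.
#'
#' @slot shaftLength,shaftRadius,neckLength,neckRadius,headRadius mm.
#' @slot neckShaftAngle degrees, in (90, 180).
#' @slot corticalThickness shell thickness, mm.
#' @slot corticalHU,cancellousHU HU assigned to shell / interior elements.
#' @slot huNoiseSD additive Gaussian HU noise (clamped below at 1 HU).
#' @slot waistDepth,waistPosition,waistWidth neck isthmus: maximum radius
#'   reduction (mm), its position as a fraction of the neck length measured
#'   from the shaft junction, and the Gaussian width (mm).
#' @slot trochRadius,trochLateral,trochProximal greater-trochanter bulge: a
#'   sphere of radius \code{trochRadius} (0 disables it) centred
#'   \code{trochLateral} mm lateral of the shaft axis and
#'   \code{trochProximal} mm proximal of the neck-shaft junction.  Its
#'   interior is cancellous under the usual cortical shell, emulating the
#'   trabecular trochanteric mass that receives the sideways-fall impact.
#' @slot targetEdgeLength maximum tetrahedron edge length, mm.
#' @slot seed integer RNG seed used for the HU noise.
#' @export
setClass("PhantomSpec",
  representation(
    shaftLength = "numeric", shaftRadius = "numeric",
    neckLength = "numeric", neckRadius = "numeric", headRadius = "numeric",
    neckShaftAngle = "numeric", corticalThickness = "numeric",
    corticalHU = "numeric", cancellousHU = "numeric", huNoiseSD = "numeric",
    waistDepth = "numeric", waistPosition = "numeric", waistWidth = "numeric",
    trochRadius = "numeric", trochLateral = "numeric",
    trochProximal = "numeric",
    targetEdgeLength = "numeric", seed = "integer"),
  prototype(
    shaftLength = 100, shaftRadius = 14,
    neckLength = 50, neckRadius = 15, headRadius = 24,
    neckShaftAngle = 130, corticalThickness = 3,
    corticalHU = 1200, cancellousHU = 150, huNoiseSD = 20,
    waistDepth = 2, waistPosition = 0.45, waistWidth = 8,
    trochRadius = 15, trochLateral = 10, trochProximal = 8,
    targetEdgeLength = 8, seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  pos <- c(shaftLength = object@shaftLength, shaftRadius = object@shaftRadius,
           neckLength = object@neckLength, neckRadius = object@neckRadius,
           headRadius = object@headRadius,
           corticalThickness = object@corticalThickness,
           targetEdgeLength = object@targetEdgeLength)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all lengths, radii and the edge length must be positive")
  if (!(object@neckShaftAngle > 90 && object@neckShaftAngle < 180))
    msg <- c(msg, "neckShaftAngle must lie in (90, 180) degrees")
  if (object@corticalHU <= object@cancellousHU)
    msg <- c(msg, "corticalHU must exceed cancellousHU")
  if (object@huNoiseSD < 0) msg <- c(msg, "huNoiseSD must be >= 0")
  if (object@waistDepth < 0 || object@waistDepth >= object@neckRadius)
    msg <- c(msg, "waistDepth must be in [0, neckRadius)")
  if (object@waistPosition <= 0 || object@waistPosition >= 1)
    msg <- c(msg, "waistPosition must be a fraction in (0, 1)")
  if (object@trochRadius < 0)
    msg <- c(msg, "trochRadius must be >= 0 (0 disables the bulge)")
  if (object@corticalThickness >= object@neckRadius - object@waistDepth)
    msg <- c(msg, "corticalThickness must be smaller than the waisted neck radius")
  if (length(msg)) msg else TRUE
})

#' Tetrahedral mesh with per-element HU
#'
#' The single geometry carrier of the package: node coordinates (mm), 4-node
#' tetrahedra with positive signed volume, one Hounsfield-unit value per
#' element, named anatomical landmarks, and (for phantoms) the construction
#' ground truth.
#'
#' @slot nodes numeric matrix, n x 3, mm.
#' @slot elements integer matrix, m x 4, 1-based node indices; every
#'   tetrahedron has positive signed volume.
#' @slot hu numeric length m, HU per element.
#' @slot landmarks named list of 3-vectors (\code{head_centre},
#'   \code{greater_trochanter}, \code{lesser_trochanter},
#'   \code{distal_end_centre}; fixtures use end-face names).
#' @slot groundTruth list; for phantoms contains \code{neck_shaft_angle},
#'   \code{neck_axis} (unit vector from the shaft junction towards the head),
#'   \code{shaft_axis} (unit vector pointing proximally), junction and waist
#'   positions.  Empty for imported meshes.
#' @export
setClass("TetMesh",
  representation(nodes = "matrix", elements = "matrix", hu = "numeric",
                 landmarks = "list", groundTruth = "list"),
  prototype(landmarks = list(), groundTruth = list()))

setValidity("TetMesh", function(object) {
  msg <- character()
  if (!is.numeric(object@nodes) || ncol(object@nodes) != 3 ||
      anyNA(object@nodes))
    msg <- c(msg, "nodes must be a finite numeric n x 3 matrix")
  el <- object@elements
  if (ncol(el) != 4 || anyNA(el))
    msg <- c(msg, "elements must be an m x 4 index matrix")
  else {
    if (min(el) < 1 || max(el) > nrow(object@nodes))
      msg <- c(msg, "element node indices out of range")
    if (length(object@hu) != nrow(el))
      msg <- c(msg, "hu must have one value per element")
    if (!length(msg)) {
      v <- .tetVolumes(object@nodes, el)
      if (any(v <= 0))
        msg <- c(msg, sprintf("%d tetrahedra have nonpositive signed volume (first: element %d)",
                              sum(v <= 0), which(v <= 0)[1]))
    }
  }
  bad <- vapply(object@landmarks,
                function(p) !(is.numeric(p) && length(p) == 3 && all(is.finite(p))),
                logical(1))
  if (any(bad)) msg <- c(msg, "landmarks must be finite 3-vectors")
  if (length(msg)) msg else TRUE
})

#' Binned material table
#'
#' Discrete material bins approximating the continuous inhomogeneous bone
#' properties.  Each nonempty bin carries a representative ash density
#' (g/cm^3), Young's modulus E (MPa), yield stress sigma_Y (MPa) and Poisson
#' ratio nu; every element maps to exactly one bin.
#'
#' @slot bins data.frame with columns \code{bin_id}, \code{density},
#'   \code{E}, \code{sigma_Y}, \code{nu}, ordered by increasing density.
#' @slot elementBin integer, bin row index per element.
#' @slot nBins integer, the requested number of equal-width density bins.
#' @export
setClass("MaterialTable",
  representation(bins = "data.frame", elementBin = "integer",
                 nBins = "integer"))

setValidity("MaterialTable", function(object) {
  b <- object@bins
  msg <- character()
  need <- c("bin_id", "density", "E", "sigma_Y", "nu")
  if (!all(need %in% names(b))) {
    msg <- c(msg, "bins must have columns bin_id, density, E, sigma_Y, nu")
  } else {
    if (any(b$E <= 0) || any(b$sigma_Y <= 0))
      msg <- c(msg, "E and sigma_Y must be positive in every bin")
    if (any(b$nu <= 0) || any(b$nu >= 0.5))
      msg <- c(msg, "nu must lie in (0, 0.5)")
    if (is.unsorted(b$density))
      msg <- c(msg, "bins must be ordered by density")
  }
  if (object@nBins < 1L) msg <- c(msg, "nBins must be >= 1")
  if (anyNA(object@elementBin) || length(object@elementBin) == 0 ||
      min(object@elementBin) < 1 || max(object@elementBin) > nrow(b))
    msg <- c(msg, "every element must map to exactly one existing bin")
  if (length(msg)) msg else TRUE
})

#' Load case: configuration, forces and supports
#'
#' Nodal force and constraint sets for the single-leg stance or sideways-fall
#' configuration.  Forces are in N; the per-node forces of the loaded set sum
#' to the total force along the load direction.  Constraints are stored as
#' fully fixed global degrees of freedom plus optional single-direction
#' (oblique) nodal constraints.
#'
#' @slot configuration \code{"stance"}, \code{"fall"} or \code{"custom"}.
#' @slot bodyWeight,height subject body weight (N) and height (cm); NA for
#'   custom cases.
#' @slot totalForce applied force magnitude, N.
#' @slot direction unit load direction.
#' @slot loadedNodes integer node indices carrying forces.
#' @slot nodeForces numeric matrix (length(loadedNodes) x 3), N.
#' @slot fixedDofs integer global DOF indices (3*(node-1)+axis) held at zero.
#' @slot directionalNodes integer nodes constrained along
#'   \code{directionalDir} only (zero displacement component).
#' @slot directionalDir unit 3-vector (empty when unused).
#' @export
setClass("LoadCase",
  representation(configuration = "character", bodyWeight = "numeric",
                 height = "numeric", totalForce = "numeric",
                 direction = "numeric", loadedNodes = "integer",
                 nodeForces = "matrix", fixedDofs = "integer",
                 directionalNodes = "integer", directionalDir = "numeric"),
  prototype(directionalNodes = integer(), directionalDir = numeric()))

setValidity("LoadCase", function(object) {
  msg <- character()
  if (length(object@loadedNodes) == 0)
    msg <- c(msg, "load case has an empty loaded node set")
  if (length(object@fixedDofs) == 0)
    msg <- c(msg, "load case has no fixed degrees of freedom")
  if (nrow(object@nodeForces) != length(object@loadedNodes))
    msg <- c(msg, "nodeForces must have one row per loaded node")
  fsum <- colSums(object@nodeForces)
  target <- object@totalForce * object@direction
  if (sqrt(sum((fsum - target)^2)) > 1e-9 * max(object@totalForce, 1))
    msg <- c(msg, "per-node forces do not sum to totalForce * direction")
  fixedNodes <- unique((object@fixedDofs - 1L) %/% 3L + 1L)
  if (length(intersect(fixedNodes, object@loadedNodes)))
    msg <- c(msg, "fixed and loaded node sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Finite element solution fields
#'
#' Nodal displacements and per-element recovered fields from a linear
#' elastostatic solve on 4-node tetrahedra (mm-N-MPa unit system).  Strain and
#' stress are stored in Voigt order (xx, yy, zz, xy, yz, zx) with engineering
#' shear strains; each is constant over a linear tetrahedron.
#'
#' @slot displacements n x 3 matrix, mm.
#' @slot strain,stress m x 6 Voigt matrices (dimensionless / MPa).
#' @slot energyDensity strain-energy density per element, N.mm/mm^3.
#' @slot vmStress,vmStrain von Mises equivalent stress (MPa) and strain.
#' @slot totalEnergy total stored strain energy, N.mm.
#' @slot externalWork half the work of the applied nodal forces, N.mm
#'   (equals \code{totalEnergy} by Clapeyron's theorem).
#' @slot volumes element volumes, mm^3.
#' @slot load the \linkS4class{LoadCase} that was solved.
#' @export
setClass("FESolution",
  representation(displacements = "matrix", strain = "matrix",
                 stress = "matrix", energyDensity = "numeric",
                 vmStress = "numeric", vmStrain = "numeric",
                 totalEnergy = "numeric", externalWork = "numeric",
                 volumes = "numeric", load = "LoadCase"))

#' Femoral coordinate axes
#'
#' Head centre and radius from a least-squares sphere fit, and the neck and
#' shaft axes as unit directions with a point on each line.  By convention
#' \code{neckDir} points away from the head centre (towards the shaft) and
#' \code{shaftDir} points proximally, so the neck-shaft angle
#' \code{acos(neckDir . shaftDir)} lies in (90, 180) degrees for anatomical
#' geometries.
#'
#' @slot headCentre,headRadius fitted femoral head sphere (mm).
#' @slot neckDir,neckPoint,shaftDir,shaftPoint unit directions and points.
#' @slot angle neck-shaft angle, degrees.
#' @export
setClass("FemoralAxes",
  representation(headCentre = "numeric", headRadius = "numeric",
                 neckDir = "numeric", neckPoint = "numeric",
                 shaftDir = "numeric", shaftPoint = "numeric",
                 angle = "numeric"))

setValidity("FemoralAxes", function(object) {
  msg <- character()
  for (d in list(object@neckDir, object@shaftDir))
    if (abs(sqrt(sum(d^2)) - 1) > 1e-8)
      msg <- c(msg, "axis directions must be unit vectors")
  if (length(msg)) msg else TRUE
})

#' Cross-section plane
#'
#' A plane through the femur with unit normal, an anatomical label and the
#' area (mm^2) of its polygonal intersection with the mesh.
#'
#' @slot origin,normal point on the plane and unit normal (mm).
#' @slot label one of \code{smallest_neck}, \code{intertrochanteric},
#'   \code{subtrochanteric} (or \code{custom}).
#' @slot area intersection area, mm^2.
#' @export
setClass("SectionPlane",
  representation(origin = "numeric", normal = "numeric", label = "character",
                 area = "numeric"))

setValidity("SectionPlane", function(object) {
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-8)
    "normal must be a unit vector" else TRUE
})

#' Triangle Gaussian quadrature rule
#'
#' Symmetric quadrature rule on the reference triangle in barycentric
#' coordinates; weights sum to 1/2 (the reference-triangle area).  The 3-point
#' interior rule integrates polynomials of total degree <= 2 exactly; the
#' 7-point rule is exact to degree 5.
#'
#' @slot n number of points (3 or 7).
#' @slot bary n x 3 barycentric coordinates.
#' @slot weights length-n positive weights, sum 1/2.
#' @export
setClass("QuadratureRule",
  representation(n = "integer", bary = "matrix", weights = "numeric"))

setValidity("QuadratureRule", function(object) {
  msg <- character()
  if (any(object@weights <= 0)) msg <- c(msg, "weights must be positive")
  if (abs(sum(object@weights) - 0.5) > 1e-12)
    msg <- c(msg, "weights must sum to 1/2")
  if (any(abs(rowSums(object@bary) - 1) > 1e-12))
    msg <- c(msg, "barycentric coordinates must sum to 1")
  if (length(msg)) msg else TRUE
})

#' 2D triangulation of a cross-section
#'
#' Planar triangulation of the polygonal intersection of a cutting plane with
#' the tetrahedral mesh, expressed in the plane's orthonormal 2D frame
#' (\code{origin}, \code{basis}).  Each triangle's Jacobian determinant is
#' twice its area; the summed areas reproduce the section area.  Containing
#' tetrahedra are recorded per triangle centroid; integration-point lookups
#' are performed against \code{candidateTets} (the tetrahedra cut by the
#' plane).
#'
#' @slot plane the \linkS4class{SectionPlane} that was triangulated.
#' @slot basis 3 x 2 orthonormal in-plane basis.
#' @slot vertices V x 2 planar coordinates (mm).
#' @slot triangles m x 3 vertex indices.
#' @slot triTet integer, tetrahedron containing each triangle centroid.
#' @slot candidateTets integer, all tetrahedra intersected by the plane.
#' @slot align \code{"boundary"} (triangulation independent of the tet
#'   structure) or \code{"tets"} (triangles nested in single tetrahedra).
#' @export
setClass("SectionTriangulation",
  representation(plane = "SectionPlane", basis = "matrix",
                 vertices = "matrix", triangles = "matrix",
                 triTet = "integer", candidateTets = "integer",
                 align = "character"))

setValidity("SectionTriangulation", function(object) {
  msg <- character()
  a <- .triAreas(object@vertices, object@triangles)
  if (any(a <= 0)) msg <- c(msg, "all triangle Jacobians must be positive")
  if (object@plane@area > 0 &&
      abs(sum(a) - object@plane@area) > 1e-6 * object@plane@area)
    msg <- c(msg, "triangle areas must sum to the section area")
  if (length(msg)) msg else TRUE
})

#' Cross-section strain-energy result
#'
#' Load-induced strain energy U, yield (maximum allowable) strain energy U_Y
#' and the fracture risk index eta = U / U_Y for one cross-section, together
#' with the section maxima of the von Mises fields.  U and U_Y integrate a
#' volumetric energy density over an area and therefore carry units of energy
#' per unit thickness (N.mm/mm); the thickness factor cancels in eta.
#'
#' @slot label section label.
#' @slot area section area, mm^2.
#' @slot U,UY energies per unit thickness, N.mm/mm.
#' @slot eta fracture risk index, dimensionless; eta > 1 flags possible
#'   fracture.
#' @slot perTriangleU,perTriangleUY per-triangle contributions.
#' @slot ruleN number of quadrature points used.
#' @slot maxVmStress,maxVmStrain section maxima of the von Mises fields.
#' @export
setClass("SectionEnergyResult",
  representation(label = "character", area = "numeric", U = "numeric",
                 UY = "numeric", eta = "numeric", perTriangleU = "numeric",
                 perTriangleUY = "numeric", ruleN = "integer",
                 maxVmStress = "numeric", maxVmStrain = "numeric"))

setValidity("SectionEnergyResult", function(object) {
  msg <- character()
  if (object@U < 0) msg <- c(msg, "U must be >= 0")
  if (object@UY <= 0) msg <- c(msg, "UY must be > 0")
  if (length(msg)) msg else TRUE
})
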