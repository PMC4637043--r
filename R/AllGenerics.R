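#' @rdname TetMesh-accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @rdname TetMesh-accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname TetMesh-accessors
#' @export
setGeneric("elementHU", function(x) standardGeneric("elementHU"))
#' @rdname TetMesh-accessors
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))
#' @rdname TetMesh-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname TetMesh-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname TetMesh-accessors
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))
#' @rdname TetMesh-accessors
#' @export
setGeneric("tetVolumes", function(x) standardGeneric("tetVolumes"))

#' @rdname MaterialTable-accessors
#' @export
setGeneric("materialBins", function(x) standardGeneric("materialBins"))
#' @rdname MaterialTable-accessors
#' @export
setGeneric("elementBins", function(x) standardGeneric("elementBins"))
#' @rdname MaterialTable-accessors
#' @export
setGeneric("elementE", function(x) standardGeneric("elementE"))
#' @rdname MaterialTable-accessors
#' @export
setGeneric("elementYieldStress", function(x) standardGeneric("elementYieldStress"))

#' @rdname FESolution-accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))
#' @rdname FESolution-accessors
#' @export
setGeneric("elementStrain", function(x) standardGeneric("elementStrain"))
#' @rdname FESolution-accessors
#' @export
setGeneric("elementStress", function(x) standardGeneric("elementStress"))
#' @rdname FESolution-accessors
#' @export
setGeneric("energyDensity", function(x) standardGeneric("energyDensity"))
#' @rdname FESolution-accessors
#' @export
setGeneric("totalStrainEnergy", function(x) standardGeneric("totalStrainEnergy"))
#' @rdname FESolution-accessors
#' @export
setGeneric("externalWork", function(x) standardGeneric("externalWork"))

#' @rdname vonMisesFields
#' @export
setGeneric("vonMisesStress", function(x) standardGeneric("vonMisesStress"))
#' @rdname vonMisesFields
#' @export
setGeneric("vonMisesStrain", function(x) standardGeneric("vonMisesStrain"))

#' @rdname neckShaftAngle
#' @export
setGeneric("neckShaftAngle", function(x) standardGeneric("neckShaftAngle"))

#' @rdname SectionEnergyResult-accessors
#' @export
setGeneric("fri", function(x) standardGeneric("fri"))
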