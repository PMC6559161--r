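#' @include AllGenerics.R
NULL

#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @export
setGeneric("rasterOrigin", function(x) standardGeneric("rasterOrigin"))

#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @export
setGeneric("nodataValue", function(x) standardGeneric("nodataValue"))

#' @export
setGeneric("crsMode", function(x) standardGeneric("crsMode"))

#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' @export
setGeneric("plotCoords", function(x) standardGeneric("plotCoords"))

#' @export
setGeneric("plotIds", function(x) standardGeneric("plotIds"))

#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @export
setGeneric("nPlots", function(x) standardGeneric("nPlots"))

#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))

#' @export
setGeneric("modelAux", function(x) standardGeneric("modelAux"))

#' @export
setGeneric("logLikelihood", function(x) standardGeneric("logLikelihood"))

#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @export
setGeneric("predictMean", function(object, x) standardGeneric("predictMean"))
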