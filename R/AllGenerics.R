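#' @rdname SceneRaster-class
#' @param object,x a SceneRaster
#' @export
setGeneric("sceneId", function(x) standardGeneric("sceneId"))
#' @rdname SceneRaster-class
#' @export
setGeneric("acquisitionDate", function(x) standardGeneric("acquisitionDate"))
#' @rdname SceneRaster-class
#' @export
setGeneric("wrsPath", function(x) standardGeneric("wrsPath"))
#' @rdname SceneRaster-class
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))
#' @rdname SceneRaster-class
#' @param band band name, e.g. "b3" or "st"
#' @export
setGeneric("getBand", function(x, band) standardGeneric("getBand"))
#' @rdname SceneRaster-class
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))
#' @rdname SceneRaster-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname SceneRaster-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname SceneRaster-class
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname IndexStack-class
#' @param x an IndexStack
#' @export
setGeneric("indexName", function(x) standardGeneric("indexName"))
#' @rdname IndexStack-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname IndexStack-class
#' @export
setGeneric("normParams", function(x) standardGeneric("normParams"))

#' @rdname CellSet-class
#' @param x a CellSet
#' @export
setGeneric("cellsMatrix", function(x) standardGeneric("cellsMatrix"))
#' @rdname CellSet-class
#' @export
setGeneric("cellLabel", function(x) standardGeneric("cellLabel"))

#' @rdname ModelResult-class
#' @param x a ModelResult
#' @export
setGeneric("coefficientTable", function(x) standardGeneric("coefficientTable"))
#' @rdname ModelResult-class
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))
#' @rdname ModelResult-class
#' @export
setGeneric("thetaEstimate", function(x) standardGeneric("thetaEstimate"))
#' @rdname ModelResult-class
#' @export
setGeneric("dispersionRatio", function(x) standardGeneric("dispersionRatio"))
#' @rdname ModelResult-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))
#' @rdname ModelResult-class
#' @export
setGeneric("isSingular", function(x) standardGeneric("isSingular"))
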