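#' @rdname SceneRaster-class
setMethod("sceneId", "SceneRaster", function(x) x@sceneId)
#' @rdname SceneRaster-class
setMethod("acquisitionDate", "SceneRaster", function(x) x@acquisitionDate)
#' @rdname SceneRaster-class
setMethod("wrsPath", "SceneRaster", function(x) x@path)
#' @rdname SceneRaster-class
setMethod("bandNames", "SceneRaster", function(x) names(x@bands))
#' @rdname SceneRaster-class
setMethod("getBand", "SceneRaster", function(x, band) {
  if (!band %in% names(x@bands))
    stop("band '", band, "' not present; have: ",
         paste(names(x@bands), collapse = ", "))
  x@bands[[band]]
})
#' @rdname SceneRaster-class
setMethod("isScaled", "SceneRaster", function(x) x@scaled)
#' @rdname SceneRaster-class
setMethod("cellSize", "SceneRaster", function(x) x@cellSize)
#' @rdname SceneRaster-class
setMethod("gridOrigin", "SceneRaster", function(x) x@origin)
#' @rdname SceneRaster-class
setMethod("gridDim", "SceneRaster", function(x) dim(x@bands[[1L]]))

setMethod("show", "SceneRaster", function(object) {
  d <- gridDim(object)
  cat("SceneRaster", object@sceneId, "\n")
  cat("  date:", format(object@acquisitionDate), " WRS path:", object@path,
      "row:", object@row, "\n")
  cat("  grid:", d[1L], "x", d[2L], "cells of", object@cellSize, "m;",
      if (object@scaled) "physically scaled" else "raw DN", "\n")
  cat("  bands:", paste(names(object@bands), collapse = ", "), "\n")
})

setMethod("show", "SceneCatalog", function(object) {
  e <- object@entries
  cat("SceneCatalog:", nrow(e), "scenes (", sum(e$excluded), "excluded )\n")
  if (nrow(e)) cat("  dates:", format(min(e$date)), "..", format(max(e$date)),
                   " paths:", paste(sort(unique(e$path)), collapse = ","), "\n")
})

#' @rdname SceneCatalog-class
#' @param x a SceneCatalog
#' @param ... unused
#' @export
setMethod("as.data.frame", "SceneCatalog", function(x, ...) x@entries)

#' @rdname SceneCatalog-class
#' @export
setMethod("length", "SceneCatalog", function(x) nrow(x@entries))

#' @rdname IndexStack-class
setMethod("indexName", "IndexStack", function(x) x@indexName)
#' @rdname IndexStack-class
setMethod("isNormalized", "IndexStack", function(x) x@normalized)
#' @rdname IndexStack-class
setMethod("normParams", "IndexStack", function(x)
  c(mean = x@normMean, sd = x@normSd))

setMethod("show", "IndexStack", function(object) {
  cat("IndexStack:", object@indexName,
      if (object@normalized) "(z-normalized)" else "(raw)", "\n")
  cat(" ", nrow(object), "cells x", ncol(object), "scene dates\n")
  callNextMethod()
})

#' @rdname CellSet-class
setMethod("cellsMatrix", "CellSet", function(x) x@cells)
#' @rdname CellSet-class
setMethod("cellLabel", "CellSet", function(x) x@label)
#' @rdname CellSet-class
#' @export
setMethod("length", "CellSet", function(x) nrow(x@cells))

setMethod("show", "CellSet", function(object) {
  cat("CellSet '", object@label, "': ", nrow(object@cells), " cells\n", sep = "")
})

#' @rdname ModelResult-class
setMethod("coefficientTable", "ModelResult", function(x) x@coefficients)
#' @rdname ModelResult-class
setMethod("modelFamily", "ModelResult", function(x) x@family)
#' @rdname ModelResult-class
setMethod("thetaEstimate", "ModelResult", function(x) x@theta)
#' @rdname ModelResult-class
setMethod("dispersionRatio", "ModelResult", function(x) x@dispersionRatio)
#' @rdname ModelResult-class
setMethod("isConverged", "ModelResult", function(x) x@converged)
#' @rdname ModelResult-class
setMethod("isSingular", "ModelResult", function(x) x@singular)

setMethod("show", "ModelResult", function(object) {
  cat("ModelResult [", object@family, "] ", object@formula, "\n", sep = "")
  cat("  n =", object@n, " AIC =", round(object@aic, 2),
      " logLik =", round(object@loglik, 2), "\n")
  if (!is.na(object@theta)) cat("  theta =", signif(object@theta, 4), "\n")
  if (!is.na(object@dispersionRatio))
    cat("  dispersion (Pearson chi-sq / df) =",
        signif(object@dispersionRatio, 4), "\n")
  if (!object@converged) cat("  ** did not converge **\n")
  if (object@singular) cat("  ** singular fit **\n")
  print(format(object@coefficients, digits = 4), row.names = FALSE)
  if (length(object@gvif)) {
    cat("  GVIF:\n")
    print(round(object@gvif, 4))
  }
})

setMethod("show", "StepwiseTrace", function(object) {
  cat("StepwiseTrace:", nrow(object@steps), "removals",
      if (object@interceptOnly) "(intercept-only final)" else "", "\n")
  if (nrow(object@steps)) print(object@steps, row.names = FALSE)
  cat("Final model:\n")
  show(object@final)
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed slope =", signif(object@observed, 5),
      "; permuted p =", signif(object@p, 4),
      "(", object@nPerm, "permutations, seed", object@seed, ")\n")
})
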