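#' @import methods
#' @importFrom stats coef sd var cor median quantile setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame
NULL

setOldClass("Date")

#' SceneRaster: one dated multiband satellite scene
#'
#' Container for a single acquisition of a Landsat-5-TM-like sensor: six
#' reflectance bands (b1, b2, b3, b4, b5, b7) and one thermal surface
#' temperature band (st), all on a shared 30 m grid. Values are either raw
#' digital numbers (`scaled = FALSE`) or physical units (`scaled = TRUE`:
#' reflectance fraction for the optical bands, degrees for the thermal band).
#'
#' Grid convention: row 1 is the northernmost row, column 1 the westernmost
#' column. `origin` is the projected (x, y) of the grid's south-west corner;
#' a point belongs to cell (r, c) via half-open intervals `[edge, edge + cs)`
#' in both axes (west/south edges included).
#'
#' @slot sceneId character scene identifier.
#' @slot acquisitionDate Date of acquisition.
#' @slot path integer WRS path.
#' @slot row integer WRS row.
#' @slot cellSize numeric cell edge length in meters (30 for TM).
#' @slot origin numeric length-2, projected (xmin, ymin) of the grid.
#' @slot bands named list of equally sized numeric matrices.
#' @slot scaled logical, whether physical scaling has been applied.
#'
#' @export
setClass("SceneRaster",
  representation(
    sceneId = "character",
    acquisitionDate = "Date",
    path = "integer",
    row = "integer",
    cellSize = "numeric",
    origin = "numeric",
    bands = "list",
    scaled = "logical"
  ),
  prototype(cellSize = 30, origin = c(0, 0), scaled = FALSE)
)

setValidity("SceneRaster", function(object) {
  msg <- character()
  if (length(object@sceneId) != 1L) msg <- c(msg, "sceneId must be length 1")
  if (length(object@acquisitionDate) != 1L || is.na(object@acquisitionDate))
    msg <- c(msg, "acquisitionDate must be a single non-missing Date")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must be length 2 (x, y)")
  if (length(object@bands) == 0L) msg <- c(msg, "at least one band required")
  dims <- vapply(object@bands, dim, integer(2))
  if (length(object@bands) > 1L && !all(dims == dims[, 1L]))
    msg <- c(msg, "all band grids must share identical dimensions")
  if (is.null(names(object@bands)) || anyDuplicated(names(object@bands)))
    msg <- c(msg, "bands must be uniquely named")
  if (length(msg)) msg else TRUE
})

#' SceneCatalog: inventory of scenes with exclusion flags
#'
#' One row per scene: identifier, acquisition date, WRS path, and an
#' exclusion flag with a mandatory reason (the reproducible replacement for
#' manual visual cloud screening).
#'
#' @slot entries data.frame with columns scene_id, date, path, excluded,
#'   reason.
#' @export
setClass("SceneCatalog", representation(entries = "data.frame"))

setValidity("SceneCatalog", function(object) {
  e <- object@entries
  need <- c("scene_id", "date", "path", "excluded", "reason")
  if (!all(need %in% names(e)))
    return(paste("catalog needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$scene_id)) return("scene_ids must be unique")
  bad <- e$excluded & (is.na(e$reason) | !nzchar(e$reason))
  if (any(bad)) return("exclusion_reason required when excluded flag is set")
  TRUE
})

#' CellSet: a labeled set of raster cells
#'
#' Stores unique (row, col) grid cells, e.g. a female's 3x3 home-range block
#' or the active landscape (union of 3x3 blocks over active mounds).
#'
#' @slot cells integer matrix with columns "row" and "col"; one row per cell.
#' @slot label character label such as "home_range" or "active_landscape".
#' @export
setClass("CellSet",
  representation(cells = "matrix", label = "character"),
  prototype(label = "cells")
)

setValidity("CellSet", function(object) {
  m <- object@cells
  if (ncol(m) != 2L) return("cells must have two columns (row, col)")
  if (nrow(m) && anyDuplicated(m)) return("duplicate cells not allowed")
  if (nrow(m) && any(m < 1L)) return("cells must have positive indices")
  TRUE
})

#' IndexStack: per-cell, per-date observations of one index
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds one spectral
#' index (Tasseled Cap brightness, greenness or wetness, or thermal surface
#' temperature) as a cells-by-scenes matrix. Rows carry grid (row, col); the
#' columns carry scene id, acquisition date and WRS path. Masked cells are NA.
#'
#' Tasseled Cap stacks may be pooled-z-normalized across all cells and dates;
#' the surface temperature stack is kept in physical units (degrees Celsius)
#' and is never normalized.
#'
#' @slot indexName one of brightness, greenness, wetness, surface_temperature.
#' @slot normalized logical; TRUE after \code{\link{zTransform}}.
#' @slot normMean,normSd pooled mean and sd removed by normalization.
#' @export
setClass("IndexStack",
  contains = "SummarizedExperiment",
  representation(
    indexName = "character",
    normalized = "logical",
    normMean = "numeric",
    normSd = "numeric"
  ),
  prototype(normalized = FALSE, normMean = NA_real_, normSd = NA_real_)
)

.INDEX_NAMES <- c("brightness", "greenness", "wetness", "surface_temperature")

setValidity("IndexStack", function(object) {
  msg <- character()
  if (!object@indexName %in% .INDEX_NAMES)
    msg <- c(msg, paste("indexName must be one of:", paste(.INDEX_NAMES, collapse = ", ")))
  if (object@indexName == "surface_temperature" && isTRUE(object@normalized))
    msg <- c(msg, "surface_temperature stacks are never normalized")
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("row", "col") %in% names(rd)))
    msg <- c(msg, "rowData must carry grid row/col")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("scene_id", "date") %in% names(cd)))
    msg <- c(msg, "colData must carry scene_id and date")
  if (isTRUE(object@normalized)) {
    v <- SummarizedExperiment::assay(object, "values")
    v <- v[!is.na(v)]
    if (length(v) > 1L &&
        (abs(mean(v)) > 1e-6 || abs(stats::sd(v) - 1) > 1e-6))
      msg <- c(msg, "normalized stack must have pooled mean 0 and sd 1")
  }
  if (length(msg)) msg else TRUE
})

#' ModelResult: a fitted model plus its diagnostics
#'
#' Uniform container for the count GLMs (Poisson / negative binomial), the
#' NB mixed model and ordinary least squares fits used across the analysis:
#' per-term coefficient table, AIC, log-likelihood, NB dispersion parameter
#' theta, Pearson dispersion ratio, per-term GVIF, and an honest convergence
#' flag.
#'
#' @slot family one of "poisson", "negbin", "gaussian", "negbin_mixed".
#' @slot formula character representation of the fitted formula.
#' @slot coefficients data.frame(term, estimate, se, statistic, p).
#' @slot theta NB dispersion parameter (NA unless family is negbin*).
#' @slot aic,loglik model fit statistics.
#' @slot dispersionRatio Pearson chi-square over residual df.
#' @slot gvif named numeric of per-term GVIF values (may be empty).
#' @slot converged,singular honest fit-status flags.
#' @slot n number of observations used after listwise deletion.
#' @slot fit the underlying fit object (for prediction).
#' @export
setClass("ModelResult",
  representation(
    family = "character",
    formula = "character",
    coefficients = "data.frame",
    theta = "numeric",
    aic = "numeric",
    loglik = "numeric",
    dispersionRatio = "numeric",
    gvif = "numeric",
    converged = "logical",
    singular = "logical",
    n = "integer",
    fit = "ANY"
  ),
  prototype(theta = NA_real_, dispersionRatio = NA_real_, gvif = numeric(),
            converged = TRUE, singular = FALSE)
)

setValidity("ModelResult", function(object) {
  msg <- character()
  if (!object@family %in% c("poisson", "negbin", "gaussian", "negbin_mixed"))
    msg <- c(msg, "unknown family")
  cf <- object@coefficients
  if (!all(c("term", "estimate", "se", "statistic", "p") %in% names(cf)))
    msg <- c(msg, "coefficients must have term/estimate/se/statistic/p")
  p <- cf$p[!is.na(cf$p)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (!is.na(object@theta) && object@theta <= 0)
    msg <- c(msg, "theta must be positive when present")
  if (length(msg)) msg else TRUE
})

#' StepwiseTrace: record of backward stepwise elimination
#'
#' @slot steps data.frame(removed_term, p_at_removal, aic_after), one row per
#'   removal in order.
#' @slot final the final \linkS4class{ModelResult}.
#' @slot interceptOnly TRUE when every candidate predictor was removed.
#' @export
setClass("StepwiseTrace",
  representation(steps = "data.frame", final = "ModelResult",
                 interceptOnly = "logical"),
  prototype(interceptOnly = FALSE)
)

#' PermutationResult: Monte-Carlo significance for a regression slope
#'
#' @slot observed observed slope coefficient.
#' @slot nPerm number of permutations.
#' @slot p add-one two-sided permuted p-value, in (0, 1].
#' @slot seed RNG seed used.
#' @export
setClass("PermutationResult",
  representation(observed = "numeric", nPerm = "integer", p = "numeric",
                 seed = "integer")
)

setValidity("PermutationResult", function(object) {
  if (object@nPerm < 1L) return("nPerm must be >= 1")
  if (object@p <= 0 || object@p > 1) return("permuted p must lie in (0, 1]")
  TRUE
})
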