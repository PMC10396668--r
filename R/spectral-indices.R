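## Tasseled Cap indices and index-stack normalization.

#' Tasseled Cap coefficients for Landsat-5 TM reflectance factors
#'
#' The Crist (1985) reflectance-factor coefficient set for TM bands
#' 1, 2, 3, 4, 5, 7 — the set used by the RStoolbox spectral-index
#' implementation. Brightness weights are all positive; greenness has
#' negative visible-band and positive near-infrared weights; wetness
#' contrasts visible/NIR against the shortwave-infrared bands.
#'
#' @return 3 x 6 numeric matrix, rows brightness/greenness/wetness, columns
#'   b1, b2, b3, b4, b5, b7.
#' @references Crist, E.P. (1985). A TM Tasseled Cap equivalent
#'   transformation for reflectance factor data. Remote Sensing of
#'   Environment 17, 301-306.
#' @export
tasseledCapCoefficients <- function() {
  m <- rbind(
    brightness = c(0.2043, 0.4158, 0.5524, 0.5741, 0.3124, 0.2303),
    greenness  = c(-0.1603, -0.2819, -0.4934, 0.7940, -0.0002, -0.1446),
    wetness    = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109)
  )
  colnames(m) <- .TM_BANDS
  m
}

#' Compute Tasseled Cap brightness, greenness and wetness for one scene
#'
#' Each index is a fixed linear combination (per-cell dot product) of the six
#' scaled reflectance bands. Masked (NA) cells stay masked.
#'
#' @param scene a scaled \linkS4class{SceneRaster} with bands b1..b5, b7.
#' @return named list of three matrices: brightness, greenness, wetness.
#' @export
tasseledCap <- function(scene) {
  if (!isScaled(scene))
    stop("scene must be scaled to reflectance before index computation")
  missing <- setdiff(.TM_BANDS, bandNames(scene))
  if (length(missing))
    stop("reflectance bands missing: ", paste(missing, collapse = ", "))
  cf <- tasseledCapCoefficients()
  d <- gridDim(scene)
  ## cells x bands matrix, then one matrix product for all three indices
  X <- vapply(.TM_BANDS, function(b) as.vector(getBand(scene, b)),
              numeric(prod(d)))
  idx <- X %*% t(cf)
  lapply(setNames(rownames(cf), rownames(cf)),
         function(k) matrix(idx[, k], d[1L], d[2L]))
}

#' Build IndexStacks from a list of scaled scenes
#'
#' Computes the three Tasseled Cap indices plus the thermal surface
#' temperature band for every scene and assembles four
#' \linkS4class{IndexStack} objects (cells x scene dates). All scenes must
#' share grid geometry; cell order is row-major on the shared grid.
#'
#' @param scenes list of scaled \linkS4class{SceneRaster} objects.
#' @return named list of four \linkS4class{IndexStack}s: brightness,
#'   greenness, wetness, surface_temperature.
#' @export
buildIndexStacks <- function(scenes) {
  stopifnot(length(scenes) >= 1L)
  d <- gridDim(scenes[[1L]])
  ok <- vapply(scenes, function(s) identical(gridDim(s), d), logical(1))
  if (!all(ok)) stop("scenes do not share grid geometry")
  ncell <- prod(d)
  dates <- as.Date(vapply(scenes, function(s) as.character(acquisitionDate(s)),
                          character(1)))
  ids <- vapply(scenes, sceneId, character(1))
  paths <- vapply(scenes, wrsPath, integer(1))
  mats <- list(brightness = NULL, greenness = NULL, wetness = NULL,
               surface_temperature = NULL)
  for (k in names(mats)) mats[[k]] <- matrix(NA_real_, ncell, length(scenes))
  for (j in seq_along(scenes)) {
    tc <- tasseledCap(scenes[[j]])
    mats$brightness[, j] <- as.vector(tc$brightness)
    mats$greenness[, j] <- as.vector(tc$greenness)
    mats$wetness[, j] <- as.vector(tc$wetness)
    mats$surface_temperature[, j] <- as.vector(getBand(scenes[[j]], "st"))
  }
  rc <- cbind(row = rep(seq_len(d[1L]), times = d[2L]),
              col = rep(seq_len(d[2L]), each = d[1L]))
  lapply(setNames(names(mats), names(mats)), function(k)
    IndexStack(mats[[k]], rowcol = rc, dates = dates, sceneIds = ids,
               paths = paths, indexName = k))
}

#' Construct an IndexStack
#'
#' @param values cells x scenes numeric matrix (NA = masked).
#' @param rowcol two-column matrix of grid (row, col) per cell.
#' @param dates acquisition dates, one per column.
#' @param sceneIds scene identifiers, one per column.
#' @param paths WRS path per column.
#' @param indexName one of brightness, greenness, wetness,
#'   surface_temperature.
#' @return an \linkS4class{IndexStack}.
#' @export
IndexStack <- function(values, rowcol, dates, sceneIds = NULL, paths = NULL,
                       indexName = "brightness") {
  values <- as.matrix(values)
  if (is.null(sceneIds)) sceneIds <- paste0("scene", seq_len(ncol(values)))
  if (is.null(paths)) paths <- rep(NA_integer_, ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    rowData = S4Vectors::DataFrame(row = as.integer(rowcol[, 1L]),
                                   col = as.integer(rowcol[, 2L])),
    colData = S4Vectors::DataFrame(scene_id = as.character(sceneIds),
                                   date = as.Date(dates),
                                   path = as.integer(paths))
  )
  new("IndexStack", se, indexName = indexName, normalized = FALSE,
      normMean = NA_real_, normSd = NA_real_)
}

#' Pooled z-transform of an IndexStack
#'
#' Centers and scales every value by the mean and sample (n-1) standard
#' deviation pooled over all non-masked cells of all scene dates, so values
#' are comparable across the whole retained scene set. The pooled parameters
#' are recorded for inversion. Surface-temperature stacks are refused: they
#' stay in physical units.
#'
#' @param stack a non-normalized \linkS4class{IndexStack}.
#' @return the normalized \linkS4class{IndexStack}.
#' @export
zTransform <- function(stack) {
  stopifnot(is(stack, "IndexStack"))
  if (isNormalized(stack)) stop("stack is already normalized")
  if (indexName(stack) == "surface_temperature")
    stop("surface_temperature is kept in physical units, not normalized")
  v <- SummarizedExperiment::assay(stack, "values")
  obs <- v[!is.na(v)]
  if (length(obs) < 2L || min(obs) == max(obs))
    stop("degenerate stack: fewer than 2 distinct values, zero pooled variance")
  m <- mean(obs)
  s <- stats::sd(obs)
  SummarizedExperiment::assay(stack, "values") <- (v - m) / s
  stack@normalized <- TRUE
  stack@normMean <- m
  stack@normSd <- s
  validObject(stack)
  stack
}

#' Invert a pooled z-transform
#'
#' @param stack a normalized \linkS4class{IndexStack}.
#' @return the stack on its original scale.
#' @export
zInverse <- function(stack) {
  if (!isNormalized(stack)) stop("stack is not normalized")
  v <- SummarizedExperiment::assay(stack, "values")
  SummarizedExperiment::assay(stack, "values") <-
    v * stack@normSd + stack@normMean
  stack@normalized <- FALSE
  stack@normMean <- NA_real_
  stack@normSd <- NA_real_
  stack
}

#' Pearson correlation with pairwise-complete masking
#'
#' Standard product-moment coefficient over pairs where both values are
#' observed; errors (rather than returning NA) when fewer than 3 complete
#' pairs remain or either vector is constant.
#'
#' @param x,y equal-length numeric vectors (NA = masked).
#' @return Pearson's r.
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs")
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x[ok], y[ok])
}

#' Pairwise correlation matrix across index stacks
#'
#' @param stacks named list of \linkS4class{IndexStack}s on a shared
#'   cells-by-dates layout.
#' @return symmetric matrix of Pearson coefficients.
#' @export
indexCorrelationMatrix <- function(stacks) {
  vals <- lapply(stacks, function(s)
    as.vector(SummarizedExperiment::assay(s, "values")))
  n <- length(vals)
  r <- diag(1, n)
  dimnames(r) <- list(names(stacks), names(stacks))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    r[i, j] <- r[j, i] <- pearsonCorrelation(vals[[i]], vals[[j]])
  r
}

#' Per-scene mean series over a cell set
#'
#' For each acquisition date, the mean and sample sd of an index over the
#' non-masked cells of `cellSet` — the diagnostic series used to spot
#' cross-path bias and seasonal structure. A date with every cell masked
#' yields a missing mean with a warning.
#'
#' @param stacks named list of \linkS4class{IndexStack}s.
#' @param cellSet a \linkS4class{CellSet}.
#' @return data.frame(date, path, index, mean, sd, n).
#' @export
sceneMeanSeries <- function(stacks, cellSet) {
  stopifnot(length(cellSet) >= 1L)
  out <- list()
  for (k in names(stacks)) {
    s <- stacks[[k]]
    ridx <- .cellset_rows(s, cellSet)
    v <- SummarizedExperiment::assay(s, "values")[ridx, , drop = FALSE]
    cd <- SummarizedExperiment::colData(s)
    mu <- colMeans(v, na.rm = TRUE)
    nobs <- colSums(!is.na(v))
    sdv <- apply(v, 2L, function(col) {
      col <- col[!is.na(col)]
      if (length(col) < 2L) 0 else stats::sd(col)
    })
    if (any(nobs == 0L)) {
      warning("all cells masked at ", sum(nobs == 0L), " dates for ", k)
      mu[nobs == 0L] <- NA_real_
    }
    out[[k]] <- data.frame(date = as.Date(cd$date), path = cd$path, index = k,
                           mean = unname(mu), sd = unname(sdv),
                           n = unname(nobs))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## map a CellSet to assay row indices of an IndexStack
.cellset_rows <- function(stack, cellSet) {
  rd <- SummarizedExperiment::rowData(stack)
  stride <- max(rd$row) + 1L
  cm <- cellsMatrix(cellSet)
  idx <- match(cm[, 1L] + cm[, 2L] * stride, rd$row + rd$col * stride)
  if (anyNA(idx)) stop("cell set contains cells outside the stack grid")
  idx
}
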