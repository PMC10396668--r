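## Scene ingestion, physical scaling, cropping and catalog filtering.
##
## Scenes are stored on disk as one plain TIFF per band, named
## `<scene_id>_<band>.tif`, with an ESRI world file (`.tfw`) sidecar per band
## carrying the georeferencing (pixel size and the projected coordinates of
## the upper-left pixel center). Band values are unsigned 16-bit digital
## numbers, exactly the encoding of Collection-2 Level-2 products.

## Landsat Collection 2 Level 2 physical scaling constants.
.REFL_GAIN <- 2.75e-05
.REFL_OFFSET <- -0.2
.TEMP_GAIN <- 0.00341802
.TEMP_OFFSET <- 149
.TM_BANDS <- c("b1", "b2", "b3", "b4", "b5", "b7")
.ALL_BANDS <- c(.TM_BANDS, "st")

#' Construct a SceneRaster
#'
#' @param sceneId scene identifier.
#' @param acquisitionDate acquisition date (Date or coercible string).
#' @param bands named list of numeric matrices with identical dimensions.
#' @param path,row WRS path and row.
#' @param cellSize cell edge in meters.
#' @param origin projected (xmin, ymin) of the grid's south-west corner.
#' @param scaled TRUE when values are already in physical units.
#' @return a \linkS4class{SceneRaster}.
#' @export
SceneRaster <- function(sceneId, acquisitionDate, bands, path = 35L, row = 38L,
                        cellSize = 30, origin = c(0, 0), scaled = FALSE) {
  new("SceneRaster", sceneId = as.character(sceneId),
      acquisitionDate = as.Date(acquisitionDate), bands = bands,
      path = as.integer(path), row = as.integer(row),
      cellSize = as.numeric(cellSize), origin = as.numeric(origin),
      scaled = isTRUE(scaled))
}

.read_worldfile <- function(path) {
  v <- as.numeric(readLines(path, n = 6L))
  if (length(v) != 6L || anyNA(v)) stop("malformed world file: ", path)
  if (v[2L] != 0 || v[3L] != 0)
    stop("rotated grids are not supported (world file ", path, ")")
  list(cs_x = v[1L], cs_y = abs(v[4L]), ulx_center = v[5L], uly_center = v[6L])
}

#' Read a multiband scene from per-band TIFF files
#'
#' Expects files `<scene_id>_<band>.tif` (+ matching `.tfw` world files) in
#' `dir` for every band in `bandLayout`. All bands must share grid size and
#' georeferencing.
#'
#' @param dir directory holding the band files.
#' @param sceneId scene identifier (file prefix).
#' @param acquisitionDate acquisition date.
#' @param bandLayout character vector of band names to read.
#' @param path,row WRS path/row of the scene.
#' @return an unscaled \linkS4class{SceneRaster} (digital numbers).
#' @export
readScene <- function(dir, sceneId, acquisitionDate,
                      bandLayout = .ALL_BANDS, path = 35L, row = 38L) {
  bands <- list()
  geo <- NULL
  for (b in bandLayout) {
    f <- file.path(dir, paste0(sceneId, "_", b, ".tif"))
    if (!file.exists(f))
      stop("band-layout error: band '", b, "' missing for scene ", sceneId)
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (!is.matrix(m)) m <- m[, , 1L]
    storage.mode(m) <- "double"
    wf <- .read_worldfile(sub("\\.tif$", ".tfw", f))
    g <- c(wf$cs_x, wf$cs_y, wf$ulx_center, wf$uly_center, dim(m))
    if (is.null(geo)) geo <- g
    else if (!isTRUE(all.equal(geo, g, tolerance = 1e-9)))
      stop("georeferencing mismatch between bands of scene ", sceneId)
    bands[[b]] <- m
  }
  cs <- geo[1L]
  if (abs(geo[2L] - cs) > 1e-9) stop("non-square cells are not supported")
  nr <- geo[5L]
  xmin <- geo[3L] - cs / 2
  ymin <- geo[4L] + cs / 2 - nr * cs
  SceneRaster(sceneId, acquisitionDate, bands, path = path, row = row,
              cellSize = cs, origin = c(xmin, ymin), scaled = FALSE)
}

#' Write a SceneRaster as per-band TIFF files with world-file sidecars
#'
#' Digital numbers are written as unsigned 16-bit TIFF; the scene must
#' therefore be unscaled with values in [0, 65535].
#'
#' @param scene an unscaled \linkS4class{SceneRaster}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeScene <- function(scene, dir) {
  if (isScaled(scene)) stop("write unscaled digital numbers, not scaled values")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- cellSize(scene)
  d <- gridDim(scene)
  ul_x <- gridOrigin(scene)[1L] + cs / 2
  ul_y <- gridOrigin(scene)[2L] + d[1L] * cs - cs / 2
  tfw <- c(cs, 0, 0, -cs, ul_x, ul_y)
  paths <- character()
  for (b in bandNames(scene)) {
    m <- getBand(scene, b)
    if (any(m < 0 | m > 65535, na.rm = TRUE))
      stop("DN values outside the 16-bit range in band ", b)
    f <- file.path(dir, paste0(sceneId(scene), "_", b, ".tif"))
    tiff::writeTIFF(round(m) / 65535, f, bits.per.sample = 16L,
                    compression = "none")
    writeLines(format(tfw, scientific = FALSE, trim = TRUE),
               sub("\\.tif$", ".tfw", f))
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Scale reflectance digital numbers to surface reflectance
#'
#' Applies the Collection-2 Level-2 affine scaling
#' `reflectance = dn * 0.0000275 - 0.2`, element-wise. Fill values should be
#' masked to NA beforehand; NAs propagate.
#'
#' @param dn numeric scalar, vector or matrix of digital numbers.
#' @param fill optional fill sentinel masked to NA before scaling.
#' @return scaled reflectance with the shape of `dn`.
#' @export
scaleReflectance <- function(dn, fill = NULL) {
  if (!is.null(fill)) {
    dn[if (length(fill) == 1L) !is.na(dn) & dn == fill else dn %in% fill] <-
      NA_real_
  }
  dn * .REFL_GAIN + .REFL_OFFSET
}

#' Scale thermal digital numbers to surface temperature
#'
#' Applies `kelvin = dn * 0.00341802 + 149`; `celsius = kelvin - 273.15`.
#'
#' @param dn numeric digital numbers.
#' @param unit "kelvin" or "celsius".
#' @param fill optional fill sentinel masked to NA before scaling.
#' @return temperature in the requested unit.
#' @export
scaleTemperature <- function(dn, unit = c("kelvin", "celsius"), fill = NULL) {
  unit <- match.arg(unit)
  if (!is.null(fill)) {
    dn[if (length(fill) == 1L) !is.na(dn) & dn == fill else dn %in% fill] <-
      NA_real_
  }
  k <- dn * .TEMP_GAIN + .TEMP_OFFSET
  if (unit == "celsius") k - 273.15 else k
}

#' Physically scale every band of a scene
#'
#' Reflectance bands get the reflectance scaling, the thermal band the
#' temperature scaling (to the requested unit). Values of `fill` are masked
#' to NA first and excluded from all downstream means. Scaled reflectance
#' outside the plausibility interval triggers a warning.
#'
#' @param scene an unscaled \linkS4class{SceneRaster}.
#' @param unit temperature unit, "celsius" (default) or "kelvin".
#' @param fill fill sentinel (default 0, the Landsat nodata DN).
#' @param plausibility allowed reflectance interval, default c(-0.2, 1.6).
#' @return the scaled \linkS4class{SceneRaster}.
#' @export
scaleScene <- function(scene, unit = "celsius", fill = 0,
                       plausibility = c(-0.2, 1.6)) {
  if (isScaled(scene)) stop("scene is already scaled")
  bands <- scene@bands
  for (b in names(bands)) {
    if (b == "st") bands[[b]] <- scaleTemperature(bands[[b]], unit, fill = fill)
    else {
      v <- scaleReflectance(bands[[b]], fill = fill)
      out <- !is.na(v) & (v < plausibility[1L] | v > plausibility[2L])
      if (any(out))
        warning(sum(out), " implausible reflectance values in band ", b,
                " of scene ", sceneId(scene))
      bands[[b]] <- v
    }
  }
  initialize(scene, bands = bands, scaled = TRUE)
}

#' Crop a scene to a projected extent
#'
#' Extent edges are snapped outward to whole-cell boundaries so every cell
#' intersecting the requested extent is kept; values are unchanged.
#'
#' @param scene a \linkS4class{SceneRaster}.
#' @param extent numeric (xmin, ymin, xmax, ymax) in projected meters.
#' @return the cropped \linkS4class{SceneRaster}.
#' @export
cropToExtent <- function(scene, extent) {
  stopifnot(length(extent) == 4L)
  cs <- cellSize(scene)
  d <- gridDim(scene)
  x0 <- gridOrigin(scene)[1L]
  y0 <- gridOrigin(scene)[2L]
  ytop <- y0 + d[1L] * cs
  c0 <- max(0L, floor((extent[1L] - x0) / cs))
  c1 <- min(d[2L], ceiling((extent[3L] - x0) / cs))
  r0 <- max(0L, floor((ytop - extent[4L]) / cs))
  r1 <- min(d[1L], ceiling((ytop - extent[2L]) / cs))
  if (c1 <= c0 || r1 <= r0) stop("empty crop: extent does not overlap scene")
  rows <- (r0 + 1L):r1
  cols <- (c0 + 1L):c1
  bands <- lapply(scene@bands, function(m) m[rows, cols, drop = FALSE])
  initialize(scene, bands = bands,
             origin = c(x0 + c0 * cs, ytop - r1 * cs))
}

#' Construct a SceneCatalog
#'
#' @param entries data.frame with columns scene_id, date, path, excluded,
#'   reason (reason required wherever excluded is TRUE).
#' @return a \linkS4class{SceneCatalog}.
#' @export
SceneCatalog <- function(entries) {
  entries$scene_id <- as.character(entries$scene_id)
  entries$date <- as.Date(entries$date)
  entries$path <- as.integer(entries$path)
  entries$excluded <- as.logical(entries$excluded)
  entries$reason <- as.character(entries$reason)
  new("SceneCatalog", entries = entries)
}

#' Read a scene catalog CSV
#'
#' Expected columns: `scene_id,date,path,row,excluded,reason`.
#'
#' @param file CSV path.
#' @return a \linkS4class{SceneCatalog}.
#' @export
readSceneCatalog <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (is.null(df$reason)) df$reason <- ""
  df$reason[is.na(df$reason)] <- ""
  SceneCatalog(df)
}

#' Filter a scene catalog by WRS path and date window
#'
#' Retains non-excluded scenes on the requested path whose acquisition date
#' falls in the half-open window `[from, to)`, in stable date order. The
#' per-path restriction reflects the cross-path bias diagnostic: index means
#' computed from one path can sit systematically higher than temporally
#' adjacent means from the other, so analyses use a single path.
#'
#' @param catalog a \linkS4class{SceneCatalog}.
#' @param wrsPath WRS path to keep (NULL keeps all paths).
#' @param from,to date window, half-open `[from, to)`.
#' @return the filtered \linkS4class{SceneCatalog}.
#' @export
filterSceneSet <- function(catalog, wrsPath = NULL, from = NULL, to = NULL) {
  e <- as.data.frame(catalog)
  keep <- !e$excluded
  if (!is.null(wrsPath)) keep <- keep & e$path %in% as.integer(wrsPath)
  if (!is.null(from)) keep <- keep & e$date >= as.Date(from)
  if (!is.null(to)) keep <- keep & e$date < as.Date(to)
  e <- e[keep, , drop = FALSE]
  e <- e[order(e$date), , drop = FALSE]
  if (nrow(e) == 0L) warning("no scenes left after filtering")
  rownames(e) <- NULL
  SceneCatalog(e)
}
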