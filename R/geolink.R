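## Registration of mound coordinates to the raster grid, home-range
## neighborhoods and the active landscape.

#' Grid geometry descriptor
#'
#' Light-weight description of the cropped raster grid: dimensions, cell
#' size and projected origin. Row 1 is the northernmost row; a point belongs
#' to cell (r, c) via half-open intervals `[edge, edge + cellSize)` on both
#' axes.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param cellSize cell edge in meters.
#' @param origin projected (xmin, ymin) of the grid's south-west corner.
#' @return a list of class "gridGeometry".
#' @export
gridGeometry <- function(nrow, ncol, cellSize = 30, origin = c(0, 0)) {
  stopifnot(nrow >= 1L, ncol >= 1L, cellSize > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellSize = as.numeric(cellSize),
                 origin = as.numeric(origin)),
            class = "gridGeometry")
}

#' Grid geometry of a SceneRaster
#' @param scene a \linkS4class{SceneRaster}.
#' @return a "gridGeometry" list.
#' @export
sceneGeometry <- function(scene) {
  d <- gridDim(scene)
  gridGeometry(d[1L], d[2L], cellSize(scene), gridOrigin(scene))
}

#' Construct a CellSet
#'
#' @param cells two-column matrix or data.frame of (row, col); duplicates are
#'   removed.
#' @param label descriptive label.
#' @return a \linkS4class{CellSet}.
#' @export
CellSet <- function(cells, label = "cells") {
  m <- as.matrix(cells)
  if (length(m) == 0L) m <- matrix(integer(), 0L, 2L)
  storage.mode(m) <- "integer"
  colnames(m) <- c("row", "col")
  m <- unique(m)
  rownames(m) <- NULL
  new("CellSet", cells = m, label = label)
}

#' Least-squares registration of the local survey frame to map coordinates
#'
#' Fits the transform mapping site-survey meter coordinates onto projected
#' map coordinates from anchor mounds known in both frames. The default is a
#' similarity transform (translation + rotation + uniform scale; a surveyed
#' meter grid should preserve angles), estimated by the closed-form
#' orthogonal-Procrustes solution; `kind = "affine"` fits a full 6-parameter
#' affine by least squares.
#'
#' @param local n x 2 matrix of survey-frame coordinates.
#' @param map n x 2 matrix of matching projected coordinates.
#' @param kind "similarity" (default) or "affine".
#' @param warnRms RMS residual (m) above which a registration warning is
#'   raised; default 15 (half a cell).
#' @return list with `transform(xy)` closure, `A` (2 x 2 linear part), `t`
#'   (translation), `scale`, `rotation` (radians, similarity only), `rms`,
#'   and per-anchor `residuals`.
#' @export
fitLocalToMapTransform <- function(local, map, kind = c("similarity", "affine"),
                                   warnRms = 15) {
  kind <- match.arg(kind)
  local <- as.matrix(local); map <- as.matrix(map)
  stopifnot(ncol(local) == 2L, ncol(map) == 2L, nrow(local) == nrow(map))
  n <- nrow(local)
  if (n < 3L) stop("registration error: need at least 3 anchor mounds")
  if (qr(sweep(local, 2L, colMeans(local)))$rank < 2L)
    stop("registration error: collinear anchor mounds")
  if (kind == "similarity") {
    mu_p <- colMeans(local); mu_q <- colMeans(map)
    P <- sweep(local, 2L, mu_p); Q <- sweep(map, 2L, mu_q)
    S <- crossprod(P, Q) / n               # 2x2 cross-covariance
    sv <- svd(S)
    D <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$v %*% D %*% t(sv$u)            # rotation (det +1)
    scl <- sum(diag(D %*% diag(sv$d))) / mean(rowSums(P^2))
    A <- scl * R
    t_vec <- mu_q - as.vector(A %*% mu_p)
    rotation <- atan2(R[2L, 1L], R[1L, 1L])
  } else {
    X <- cbind(1, local)
    B <- qr.solve(X, map)                  # 3x2: intercepts + linear part
    A <- t(B[2:3, , drop = FALSE])
    t_vec <- B[1L, ]
    scl <- sqrt(abs(det(A)))
    rotation <- NA_real_
  }
  fitted <- sweep(local %*% t(A), 2L, -t_vec)
  res <- sqrt(rowSums((map - fitted)^2))
  rms <- sqrt(mean(res^2))
  if (rms > warnRms)
    warning("registration RMS residual ", round(rms, 2), " m exceeds ",
            warnRms, " m")
  list(transform = function(xy) {
         xy <- as.matrix(xy)
         if (ncol(xy) != 2L) xy <- matrix(xy, ncol = 2L)
         sweep(xy %*% t(A), 2L, -t_vec)
       },
       A = A, t = t_vec, scale = scl, rotation = rotation,
       rms = rms, residuals = res)
}

#' Assign a projected point to its raster cell
#'
#' Half-open convention: a point on a shared west/south cell edge belongs to
#' the cell east/north of the edge (intervals `[edge, edge + cellSize)`).
#'
#' @param xy numeric (x, y) or n x 2 matrix of projected points.
#' @param geom a "gridGeometry".
#' @return integer (row, col), or an n x 2 matrix for matrix input.
#' @export
assignCell <- function(xy, geom) {
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2L)
  cs <- geom$cellSize
  colj <- floor((m[, 1L] - geom$origin[1L]) / cs) + 1L
  ## rows count from the north: the top row covers the highest y interval
  rowi <- geom$nrow - floor((m[, 2L] - geom$origin[2L]) / cs)
  bad <- colj < 1L | colj > geom$ncol | rowi < 1L | rowi > geom$nrow
  if (any(bad)) stop("point outside grid extent (", sum(bad), " points)")
  out <- cbind(row = as.integer(rowi), col = as.integer(colj))
  if (is.matrix(xy)) out else out[1L, ]
}

#' Center coordinates of raster cells
#'
#' @param cells two-column (row, col) matrix.
#' @param geom a "gridGeometry".
#' @return n x 2 matrix of projected cell-center (x, y).
#' @export
cellCenters <- function(cells, geom) {
  cells <- rbind(cells)
  cs <- geom$cellSize
  x <- geom$origin[1L] + (cells[, 2L] - 0.5) * cs
  y <- geom$origin[2L] + (geom$nrow - cells[, 1L] + 0.5) * cs
  cbind(x = x, y = y)
}

#' 3x3 home-range neighborhood of a cell
#'
#' The cell containing a mound plus its eight adjacent cells — the fixed
#' home-range definition (with 30 m cells the center-to-outer-corner
#' distance is 45 * sqrt(2), about 63 m). Cells falling outside the grid are
#' dropped, so edge and corner cells yield 6 and 4 cells respectively.
#'
#' @param cell integer (row, col).
#' @param geom a "gridGeometry".
#' @return a \linkS4class{CellSet} labeled "home_range".
#' @export
neighborhood3x3 <- function(cell, geom) {
  r <- cell[1L]; cl <- cell[2L]
  if (r < 1L || r > geom$nrow || cl < 1L || cl > geom$ncol)
    stop("cell out of grid bounds")
  g <- expand.grid(row = (r - 1L):(r + 1L), col = (cl - 1L):(cl + 1L))
  g <- g[g$row >= 1L & g$row <= geom$nrow & g$col >= 1L & g$col <= geom$ncol, ]
  CellSet(as.matrix(g), label = "home_range")
}

#' Active landscape: union of 3x3 neighborhoods over active cells
#'
#' All cells containing an active mound plus the eight cells adjacent to
#' each, deduplicated.
#'
#' @param activeCells two-column (row, col) matrix of active-mound cells.
#' @param geom a "gridGeometry".
#' @return a \linkS4class{CellSet} labeled "active_landscape".
#' @export
activeLandscape <- function(activeCells, geom) {
  activeCells <- rbind(activeCells)
  if (nrow(activeCells) == 0L) {
    warning("no active cells: empty landscape")
    return(CellSet(matrix(integer(), 0L, 2L), label = "active_landscape"))
  }
  blocks <- lapply(seq_len(nrow(activeCells)), function(i)
    cellsMatrix(neighborhood3x3(activeCells[i, ], geom)))
  CellSet(do.call(rbind, blocks), label = "active_landscape")
}

#' Assign mounds to raster cells
#'
#' Mounds with GPS (projected) coordinates are assigned directly; mounds
#' known only in the local survey frame are first registered via the
#' similarity transform fitted on the anchor mounds that carry both
#' coordinate systems. An optional override table replays manual
#' corrections.
#'
#' @param mounds data.frame with columns mound_id, gps_x, gps_y, local_x,
#'   local_y (NA where unknown).
#' @param geom a "gridGeometry".
#' @param overrides optional data.frame(mound_id, row, col) applied last.
#' @param kind transform kind passed to \code{\link{fitLocalToMapTransform}}.
#' @return data.frame(mound_id, row, col, source) with source one of
#'   "gps", "registered", "manual".
#' @export
assignMounds <- function(mounds, geom, overrides = NULL, kind = "similarity") {
  has_gps <- !is.na(mounds$gps_x) & !is.na(mounds$gps_y)
  has_loc <- !is.na(mounds$local_x) & !is.na(mounds$local_y)
  if (any(!has_gps & !has_loc))
    stop("mounds without any coordinates: ",
         paste(mounds$mound_id[!has_gps & !has_loc], collapse = ", "))
  out <- data.frame(mound_id = mounds$mound_id, row = NA_integer_,
                    col = NA_integer_, source = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(has_gps)) {
    rc <- assignCell(cbind(mounds$gps_x[has_gps], mounds$gps_y[has_gps]), geom)
    out$row[has_gps] <- rc[, 1L]; out$col[has_gps] <- rc[, 2L]
    out$source[has_gps] <- "gps"
  }
  need <- !has_gps & has_loc
  if (any(need)) {
    anchors <- has_gps & has_loc
    tr <- fitLocalToMapTransform(
      cbind(mounds$local_x[anchors], mounds$local_y[anchors]),
      cbind(mounds$gps_x[anchors], mounds$gps_y[anchors]), kind = kind)
    proj <- tr$transform(cbind(mounds$local_x[need], mounds$local_y[need]))
    rc <- assignCell(proj, geom)
    out$row[need] <- rc[, 1L]; out$col[need] <- rc[, 2L]
    out$source[need] <- "registered"
  }
  if (!is.null(overrides) && nrow(overrides)) {
    i <- match(overrides$mound_id, out$mound_id)
    out$row[i] <- as.integer(overrides$row)
    out$col[i] <- as.integer(overrides$col)
    out$source[i] <- "manual"
  }
  out
}
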