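## Lag-aligned temporal aggregation: annual (season-equalized), summer-rainy
## and winter-rainy covariate means for female home ranges and the active
## landscape, plus daily-climate summaries.

#' Meteorological season of a date
#'
#' DJF = winter, MAM = spring, JJA = summer, SON = autumn.
#'
#' @param date Date vector.
#' @return character vector of seasons.
#' @export
meteorologicalSeason <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  c("winter", "winter", "spring", "spring", "spring", "summer",
    "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Lag-aligned covariate window for a response year
#'
#' A six-month lag aligns environment with response: annual means predicting
#' offspring produced in year t use July (t-1) through June (t); means
#' predicting survival of year-t offspring to t+1 use July (t) through June
#' (t+1). The summer rainy window covers July-August at the start of the
#' annual window, the winter rainy window December 1 through March 31 inside
#' it.
#'
#' @param responseYear integer year t of the response.
#' @param windowKind "annual", "summer_rainy" or "winter_rainy".
#' @param responseKind "offspring" (default) or "survival".
#' @return list(start, end, windowKind, responseKind, responseYear); the
#'   window is the closed date interval [start, end].
#' @export
lagWindow <- function(responseYear,
                      windowKind = c("annual", "summer_rainy", "winter_rainy"),
                      responseKind = c("offspring", "survival")) {
  windowKind <- match.arg(windowKind)
  responseKind <- match.arg(responseKind)
  ## survival windows for year t equal offspring windows for year t+1
  y <- as.integer(responseYear) + (responseKind == "survival")
  d <- function(y, m, dd) as.Date(sprintf("%04d-%02d-%02d", y, m, dd))
  win <- switch(windowKind,
    annual = list(start = d(y - 1L, 7L, 1L), end = d(y, 6L, 30L)),
    summer_rainy = list(start = d(y - 1L, 7L, 1L), end = d(y - 1L, 8L, 31L)),
    winter_rainy = list(start = d(y - 1L, 12L, 1L), end = d(y, 3L, 31L)))
  c(win, list(windowKind = windowKind, responseKind = responseKind,
              responseYear = as.integer(responseYear)))
}

#' Season-equalized mean of dated observations
#'
#' Observations are bucketed by meteorological season, averaged within each
#' season, and the season means are averaged — so unevenly timed scenes
#' cannot bias the annual covariate toward densely observed seasons. Seasons
#' with no observations are omitted from the outer mean with a coverage
#' warning.
#'
#' @param values numeric observations (NA dropped).
#' @param dates matching Date vector.
#' @return scalar mean, or NA when there are no observations.
#' @export
seasonEqualizedMean <- function(values, dates) {
  ok <- !is.na(values)
  values <- values[ok]; dates <- as.Date(dates)[ok]
  if (length(values) == 0L) return(NA_real_)
  season <- meteorologicalSeason(dates)
  mu <- tapply(values, season, mean)
  if (length(mu) < 4L)
    warning("only ", length(mu), " of 4 seasons observed; ",
            "season-equalized mean computed over observed seasons")
  mean(mu)
}

#' Plain mean over a rainy-season window
#'
#' @param values numeric observations.
#' @param dates matching Date vector.
#' @param window a \code{\link{lagWindow}} with windowKind summer_rainy or
#'   winter_rainy.
#' @return mean of observations dated inside the window; NA (with a warning)
#'   when none fall inside it.
#' @export
rainySeasonMean <- function(values, dates, window) {
  if (!window$windowKind %in% c("summer_rainy", "winter_rainy"))
    stop("window must be a rainy-season window")
  dates <- as.Date(dates)
  inw <- dates >= window$start & dates <= window$end & !is.na(values)
  if (!any(inw)) {
    warning("no observations inside the ", window$windowKind, " window")
    return(NA_real_)
  }
  mean(values[inw])
}

## One-off extraction of assay matrices, dates and a (row, col) -> assay-row
## lookup so repeated unit summaries avoid S4 dispatch in inner loops.
.stack_cache <- function(stacks) {
  lapply(stacks, function(s) {
    rd <- SummarizedExperiment::rowData(s)
    L <- matrix(NA_integer_, max(rd$row), max(rd$col))
    L[cbind(rd$row, rd$col)] <- seq_len(nrow(rd))
    list(values = SummarizedExperiment::assay(s, "values"),
         dates = as.Date(SummarizedExperiment::colData(s)$date),
         lookup = L)
  })
}

.summarize_cached <- function(cache, cells, window) {
  vapply(cache, function(cc) {
    ridx <- cc$lookup[cells]
    if (anyNA(ridx)) stop("cell set contains cells outside the stack grid")
    keep <- cc$dates >= window$start & cc$dates <= window$end
    if (!any(keep)) return(NA_real_)
    v <- cc$values[ridx, keep, drop = FALSE]
    mu <- colMeans(v, na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    if (window$windowKind == "annual")
      seasonEqualizedMean(mu, cc$dates[keep])
    else rainySeasonMean(mu, cc$dates[keep], window)
  }, numeric(1))
}

#' Environmental summary of one unit (female home range or landscape)
#'
#' Per scene date, the index value is averaged over the non-masked cells of
#' `cellSet`; the per-date means are then aggregated over the lag window
#' (season-equalized for annual windows, plain for rainy-season windows).
#'
#' @param stacks named list of \linkS4class{IndexStack}s.
#' @param cellSet a \linkS4class{CellSet}.
#' @param window a \code{\link{lagWindow}}.
#' @return named numeric, one summary value per stack.
#' @export
summarizeUnit <- function(stacks, cellSet, window) {
  stopifnot(length(cellSet) >= 1L)
  .summarize_cached(.stack_cache(stacks), cellsMatrix(cellSet), window)
}

#' Summarize a daily climate series over a lag window
#'
#' Daily precipitation and temperature series are aggregated the same three
#' ways as the index stacks, so population-level predictor tables are
#' structurally uniform: annual windows use the season-equalized mean of
#' daily values, rainy-season windows the plain mean. A coverage warning is
#' raised when more than 10 percent of window days are missing.
#'
#' @param climate data.frame(date, precip, tmin, tmean, tmax).
#' @param window a \code{\link{lagWindow}}.
#' @return named numeric: precip, tmin, tmean, tmax.
#' @export
summarizeClimate <- function(climate, window) {
  d <- as.Date(climate$date)
  keep <- d >= window$start & d <= window$end
  ndays <- as.integer(window$end - window$start) + 1L
  if (sum(keep) < 0.9 * ndays)
    warning("climate series covers only ", sum(keep), " of ", ndays,
            " window days")
  vars <- c("precip", "tmin", "tmean", "tmax")
  if (sum(keep) == 0L)
    return(setNames(rep(NA_real_, 4L), vars))
  vapply(setNames(vars, vars), function(v) {
    x <- climate[[v]][keep]
    if (window$windowKind == "annual") {
      suppressWarnings(seasonEqualizedMean(x, d[keep]))
    } else mean(x, na.rm = TRUE)
  }, numeric(1))
}

#' Build the per-female-year environmental covariate table
#'
#' Joins female-year records to their home-range (3x3) cell sets and
#' computes, per female-year and window kind, the lag-aligned summaries of
#' every index stack.
#'
#' @param femaleYears data.frame with female_id, year and primary-mound
#'   grid cell columns `row`, `col` (see \code{\link{assignMounds}}).
#' @param stacks named list of \linkS4class{IndexStack}s.
#' @param geom a "gridGeometry".
#' @param windowKind window kind, default "annual".
#' @param responseKind "offspring" or "survival".
#' @return `femaleYears` with one extra numeric column per stack.
#' @export
femaleEnvTable <- function(femaleYears, stacks, geom,
                           windowKind = "annual",
                           responseKind = "offspring") {
  env <- matrix(NA_real_, nrow(femaleYears), length(stacks),
                dimnames = list(NULL, names(stacks)))
  sc <- .stack_cache(stacks)
  ## same cell and year share a summary
  key <- paste(femaleYears$row, femaleYears$col, femaleYears$year)
  first <- !duplicated(key)
  cache <- list()
  for (i in which(first)) {
    w <- lagWindow(femaleYears$year[i], windowKind, responseKind)
    cs <- neighborhood3x3(c(femaleYears$row[i], femaleYears$col[i]), geom)
    cache[[key[i]]] <-
      suppressWarnings(.summarize_cached(sc, cellsMatrix(cs), w))
  }
  for (i in seq_len(nrow(femaleYears))) env[i, ] <- cache[[key[i]]]
  cbind(femaleYears, as.data.frame(env))
}
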