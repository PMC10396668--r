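## Shared fixture builders (all fixtures are generated in code).

## random unscaled scene with DN bands in a plausible Landsat range
makeTestScene <- function(nr = 5L, nc = 5L, seed = 1L, sceneId = "test01",
                          date = "2000-06-15", path = 35L,
                          origin = c(0, 0), bands = c(.tm_bands(), "st")) {
  set.seed(seed)
  bl <- lapply(seq_along(bands), function(i)
    matrix(sample(7000:30000, nr * nc, replace = TRUE), nr, nc))
  names(bl) <- bands
  SceneRaster(sceneId, date, bl, path = path, cellSize = 30, origin = origin)
}

.tm_bands <- function() c("b1", "b2", "b3", "b4", "b5", "b7")

## scaled scene with prescribed reflectance in every band
makeScaledScene <- function(refl, nr = 2L, nc = 2L, date = "2000-06-15") {
  bl <- lapply(seq_along(.tm_bands()), function(i)
    matrix(refl[i], nr, nc))
  names(bl) <- .tm_bands()
  bl$st <- matrix(20, nr, nc)
  SceneRaster("scaled01", date, bl, scaled = TRUE)
}

## IndexStack straight from a cells x dates matrix on an nr x nc grid
makeStack <- function(values, nr, nc, dates, indexName = "brightness",
                      paths = NULL) {
  rc <- cbind(row = rep(seq_len(nr), times = nc),
              col = rep(seq_len(nc), each = nr))
  IndexStack(values, rowcol = rc, dates = dates, indexName = indexName,
             paths = paths)
}

## small, fast simulation configuration for pipeline tests
smallSimConfig <- function(...) {
  simConfig(nYears = 3L, nScenes = 40L, gridShape = c(24L, 20L),
            nMounds = 30L, nAnchorMounds = 24L, nFemalesPerYear = 12L, ...)
}
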