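## End-to-end assemblies: individual-fitness, population-fitness and
## population-size analyses from the module building blocks.

#' Individual-fitness analysis table
#'
#' Builds the per-female-year response table (offspring counts, survivors,
#' primary mound), registers primary mounds to grid cells, and attaches the
#' lag-aligned environmental covariates of each female's 3x3 home range.
#'
#' @param captures,pedigree demographic input tables.
#' @param moundCells data.frame(mound_id, row, col) from
#'   \code{\link{assignMounds}} (or the generator's mound table).
#' @param stacks named list of \linkS4class{IndexStack}s.
#' @param geom grid geometry.
#' @param windowKind "annual", "summer_rainy" or "winter_rainy".
#' @param responseKind "offspring" or "survival" (controls the lag).
#' @return data.frame with response columns and one covariate column per
#'   stack.
#' @export
individualFitnessTable <- function(captures, pedigree, moundCells, stacks,
                                   geom, windowKind = "annual",
                                   responseKind = "offspring") {
  fy <- femaleYearTable(captures, pedigree)
  i <- match(fy$primary_mound, moundCells$mound_id)
  fy$row <- moundCells$row[i]
  fy$col <- moundCells$col[i]
  fy <- fy[!is.na(fy$row), , drop = FALSE]
  femaleEnvTable(fy, stacks, geom, windowKind, responseKind)
}

#' Fit and select the individual-fitness count model
#'
#' Backward stepwise negative binomial (or Poisson) regression of the chosen
#' fitness response on brightness, greenness, wetness and surface
#' temperature.
#'
#' @param envTable output of \code{\link{individualFitnessTable}}.
#' @param response "offspring" (all females) or "survival" (restricted to
#'   females with at least one offspring).
#' @param family "negbin" or "poisson".
#' @param alpha stepwise significance threshold.
#' @return a \linkS4class{StepwiseTrace}.
#' @export
fitIndividualFitness <- function(envTable, response = c("offspring",
                                                        "survival"),
                                 family = "negbin", alpha = 0.05) {
  response <- match.arg(response)
  covnames <- intersect(.INDEX_NAMES, names(envTable))
  if (response == "offspring") {
    y <- envTable$n_offspring
    X <- envTable[covnames]
  } else {
    keep <- !is.na(envTable$n_surviving) & envTable$n_offspring >= 1L
    y <- envTable$n_surviving[keep]
    X <- envTable[keep, covnames]
  }
  backwardStepwise(y, X, family = family, alpha = alpha)
}

#' Landscape-year covariate table
#'
#' For each year, the active landscape is the union of 3x3 neighborhoods
#' around cells holding a female-occupied mound that year; index stacks are
#' averaged over it with the lag-aligned window, and the daily climate
#' series is summarized the same way.
#'
#' @param captures capture table.
#' @param moundCells data.frame(mound_id, row, col).
#' @param stacks named list of \linkS4class{IndexStack}s.
#' @param geom grid geometry.
#' @param climate optional data.frame(date, precip, tmin, tmean, tmax).
#' @param windowKind window kind.
#' @param responseKind "offspring" or "survival" lag alignment.
#' @return data.frame, one row per year, with index and climate summaries.
#' @export
landscapeEnvTable <- function(captures, moundCells, stacks, geom,
                              climate = NULL, windowKind = "annual",
                              responseKind = "offspring") {
  years <- sort(unique(captures$year))
  rows <- lapply(years, function(t) {
    fem <- captures[captures$year == t & captures$sex == "F" &
                      captures$age_class == "adult", , drop = FALSE]
    i <- match(unique(fem$mound_id), moundCells$mound_id)
    i <- i[!is.na(i)]
    cells <- unique(cbind(moundCells$row[i], moundCells$col[i]))
    land <- activeLandscape(cells, geom)
    w <- lagWindow(t, windowKind, responseKind)
    env <- suppressWarnings(summarizeUnit(stacks, land, w))
    out <- data.frame(year = t, n_active_cells = length(land))
    out <- cbind(out, as.data.frame(as.list(env)))
    if (!is.null(climate)) {
      cl <- suppressWarnings(summarizeClimate(climate, w))
      out <- cbind(out, as.data.frame(as.list(cl)))
    }
    out
  })
  do.call(rbind, rows)
}

#' Single-predictor linear regressions with permutation p-values
#'
#' The population-level testing pattern: each environmental predictor is
#' regressed against the response separately by OLS, and significance is
#' assessed by permuting the response (add-one two-sided Monte-Carlo p on
#' the slope).
#'
#' @param response numeric response (one value per year).
#' @param predictors data.frame of candidate predictors (same rows).
#' @param nPerm permutations per model.
#' @param seed RNG seed.
#' @return data.frame(predictor, slope, se, t, p_lm, p_perm, adj_r_squared).
#' @export
populationRegressions <- function(response, predictors, nPerm = 1000L,
                                  seed = 1L) {
  rows <- lapply(seq_along(predictors), function(j) {
    x <- predictors[[j]]
    ok <- stats::complete.cases(response, x)
    if (sum(ok) < 3L || stats::var(x[ok]) == 0) return(NULL)
    m <- fitLm(response[ok], x[ok])
    cf <- coefficientTable(m)
    sl <- cf[cf$term == "x", ]
    pr <- permutationPvalue(response[ok], x[ok], nPerm = nPerm,
                            seed = seed + j)
    data.frame(predictor = names(predictors)[j], slope = sl$estimate,
               se = sl$se, t = sl$statistic, p_lm = sl$p, p_perm = pr@p,
               adj_r_squared = adjRSquared(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
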