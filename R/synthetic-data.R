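## Synthetic study generator: dated multiband scenes, daily climate, mound
## maps, capture/pedigree tables and NB-distributed offspring counts with
## known ground truth, at the dimensions of the field study (13 response
## years, 167 scenes, 214 mounds, ~480 female-years).

#' Simulation configuration
#'
#' Defaults mirror the study dimensions: 13 response years observed by 167
#' scenes on a 92 x 70 grid of 30 m cells, 214 mounds (188 with GPS), about
#' 37 breeding females per year, offspring counts drawn from the same
#' log-link negative binomial the inference stage fits, and a
#' brightness-wetness field correlation of 0.9. Temperature follows an
#' annual sinusoid peaking in early July. True coefficients default to the
#' annual individual-fitness model scale: brightness in pooled z-units,
#' surface temperature in degrees Celsius.
#'
#' @param nYears number of response years.
#' @param nScenes total scene count across the series.
#' @param gridShape c(nrow, ncol) of the cropped grid.
#' @param cellSize cell edge, meters.
#' @param nMounds,nAnchorMounds mound counts (anchors carry GPS).
#' @param nFemalesPerYear breeding females per year.
#' @param trueBeta named coefficients: intercept, brightness, greenness,
#'   wetness (z-units), surface_temperature (per degree C).
#' @param trueTheta NB dispersion parameter of the offspring model.
#' @param tempMean,tempAmplitude annual surface-temperature sinusoid (deg C);
#'   peak around early July, trough around January.
#' @param bwCorrelation target pooled brightness-wetness Pearson r.
#' @param survivalLogit logit-scale intercept of offspring survival to age 1.
#' @param captureProb named capture probabilities c(adult, juvenile); set
#'   both to 1 for exact bookkeeping round trips.
#' @param annualPrecip expected annual precipitation total, mm.
#' @param startYear calendar year whose July opens the scene series; the
#'   first response year is startYear + 1.
#' @return a list of class "simConfig".
#' @export
simConfig <- function(nYears = 13L, nScenes = 167L, gridShape = c(92L, 70L),
                      cellSize = 30,
                      nMounds = 214L, nAnchorMounds = 188L,
                      nFemalesPerYear = 37L,
                      trueBeta = c(intercept = -0.7191, brightness = 0.359,
                                   greenness = 0, wetness = 0,
                                   surface_temperature = 0.0382),
                      trueTheta = 2,
                      tempMean = 25, tempAmplitude = 15,
                      bwCorrelation = 0.9,
                      survivalLogit = -0.4,
                      captureProb = c(adult = 0.98, juvenile = 0.93),
                      annualPrecip = 300,
                      startYear = 1992L) {
  stopifnot(nYears >= 1L, nScenes >= 4L, all(gridShape >= 3L),
            nMounds >= nAnchorMounds, nAnchorMounds >= 3L,
            abs(bwCorrelation) < 1, trueTheta > 0,
            all(captureProb > 0 & captureProb <= 1))
  structure(as.list(environment()), class = "simConfig")
}

## Index-field structure (index units): a static spatial component, a
## per-scene temporal component and cell-by-scene noise, each correlated at
## bwCorrelation between brightness and wetness so the pooled correlation
## hits the target.
.BW_MEAN <- c(brightness = 0.32, wetness = -0.10)
.BW_SD <- c(space = 0.025, time = 0.020, noise = 0.040)
.W_SCALE <- 0.8   # wetness component sds = .W_SCALE * brightness sds
.G_MEAN <- 0.05
.G_SD <- 0.008
.ST_SPACE_SD <- 0.8
.ST_NOISE_SD <- 0.5
.TEMP_PEAK_DOY <- 187  # early July

#' Generate the synthetic scene series
#'
#' Scene dates are spread evenly from July of `startYear` to late June of
#' the final response year. Surface temperature is an annual sinusoid
#' (maximum early July, minimum around January) plus a static spatial field
#' and noise; brightness and wetness are generated as a correlated pair of
#' fields at `bwCorrelation`; greenness is low-amplitude noise. Index
#' targets are mapped back to six reflectance bands through the
#' Moore-Penrose right inverse of the Tasseled Cap coefficient matrix, so
#' the Tasseled Cap transform of the emitted bands reproduces the targets
#' exactly (up to 1-DN quantization), and digital numbers invert the
#' Collection-2 scale factors.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed RNG seed.
#' @param writeDir optional directory: scenes are also written as per-band
#'   TIFFs with world files, plus a catalog CSV.
#' @return list(scenes = list of unscaled \linkS4class{SceneRaster},
#'   catalog = \linkS4class{SceneCatalog}, geom = grid geometry,
#'   truth = noiseless field parameters and realized index targets).
#' @export
generateScenes <- function(config, seed = 1L, writeDir = NULL) {
  set.seed(seed)
  nr <- config$gridShape[1L]; nc <- config$gridShape[2L]
  ncell <- nr * nc
  ns <- config$nScenes
  d0 <- as.Date(sprintf("%d-07-03", config$startYear))
  d1 <- as.Date(sprintf("%d-06-26", config$startYear + config$nYears))
  dates <- as.Date(round(seq(as.numeric(d0), as.numeric(d1),
                             length.out = ns)), origin = "1970-01-01")
  doy <- as.integer(format(dates, "%j"))
  rho <- config$bwCorrelation
  mix <- function(z1, z2) rho * z1 + sqrt(1 - rho^2) * z2
  ## correlated components, same correlation in every variance component
  sp_b <- matrix(stats::rnorm(ncell), ncell, 1L)
  sp_w <- mix(sp_b, stats::rnorm(ncell))
  tm_b <- stats::rnorm(ns)
  tm_w <- mix(tm_b, stats::rnorm(ns))
  nz_b <- matrix(stats::rnorm(ncell * ns), ncell, ns)
  nz_w <- mix(nz_b, matrix(stats::rnorm(ncell * ns), ncell, ns))
  B <- .BW_MEAN["brightness"] + .BW_SD["space"] * sp_b[, 1L] +
    rep(.BW_SD["time"] * tm_b, each = ncell) + .BW_SD["noise"] * nz_b
  W <- .BW_MEAN["wetness"] + .W_SCALE *
    (.BW_SD["space"] * sp_w[, 1L] + rep(.BW_SD["time"] * tm_w, each = ncell) +
       .BW_SD["noise"] * nz_w)
  G <- .G_MEAN + .G_SD * matrix(stats::rnorm(ncell * ns), ncell, ns)
  st_space <- .ST_SPACE_SD * stats::rnorm(ncell)
  seas <- config$tempMean + config$tempAmplitude *
    cos(2 * pi * (doy - .TEMP_PEAK_DOY) / 365.25)
  ST <- outer(st_space, rep(1, ns)) + rep(seas, each = ncell) +
    .ST_NOISE_SD * matrix(stats::rnorm(ncell * ns), ncell, ns)
  ## map index targets to band DNs in one pass: the Moore-Penrose right
  ## inverse of the coefficient matrix sends targets to band reflectances
  ## whose Tasseled Cap transform reproduces them exactly
  C <- tasseledCapCoefficients()
  pinv <- t(C) %*% solve(C %*% t(C))   # 6x3 right inverse: C %*% pinv = I
  idx_all <- rbind(as.vector(B), as.vector(G), as.vector(W))  # 3 x (ncell*ns)
  dn_all <- round((pinv %*% idx_all + 0.2) / 2.75e-05)
  rng <- range(dn_all)
  if (rng[1L] < 1 || rng[2L] > 65535)
    stop("band DN out of range; index targets too extreme")
  st_dn <- round((ST + 273.15 - 149) / 0.00341802)
  scenes <- vector("list", ns)
  for (j in seq_len(ns)) {
    cells_j <- (j - 1L) * ncell + seq_len(ncell)
    bl <- lapply(seq_len(6L), function(b) {
      m <- dn_all[b, cells_j]
      dim(m) <- c(nr, nc)
      m
    })
    names(bl) <- .TM_BANDS
    m <- st_dn[, j]
    dim(m) <- c(nr, nc)
    bl$st <- m
    scenes[[j]] <- SceneRaster(sprintf("sim%03d", j), dates[j], bl,
                               path = 35L, row = 38L,
                               cellSize = config$cellSize, origin = c(0, 0))
  }
  catalog <- SceneCatalog(data.frame(
    scene_id = vapply(scenes, sceneId, character(1)),
    date = dates, path = 35L, excluded = FALSE, reason = "",
    stringsAsFactors = FALSE))
  if (!is.null(writeDir)) {
    for (s in scenes) writeScene(s, writeDir)
    utils::write.csv(as.data.frame(catalog),
                     file.path(writeDir, "catalog.csv"), row.names = FALSE)
  }
  list(scenes = scenes, catalog = catalog,
       geom = gridGeometry(nr, nc, config$cellSize, c(0, 0)),
       truth = list(dates = dates, seasonal_temp = seas,
                    bw_correlation = rho,
                    brightness = B, wetness = W, greenness = G,
                    surface_temperature = ST))
}

#' Generate the synthetic population: mounds, captures, pedigree
#'
#' Mounds are placed on distinct grid cells; anchor mounds carry GPS
#' (projected) coordinates, and every mound carries local survey-frame
#' coordinates under a known similarity transform (rotation + translation).
#' Each year's breeding females occupy distinct mounds; per female-year the
#' offspring count is drawn from NegBin(mean = exp(beta0 + sum(beta *
#' covariates of her 3x3 home range)), theta), using the lag-aligned annual
#' covariates computed from the supplied index stacks — the same quantities
#' the analysis pipeline later recomputes. Offspring survive to the next
#' year with logistic probability; surviving females may join the breeding
#' pool. Capture records are emitted for all living animals, optionally
#' thinned by the capture probabilities.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed RNG seed.
#' @param stacks named list of \linkS4class{IndexStack}s (Tasseled Cap
#'   stacks z-normalized, surface temperature in deg C) built from the
#'   generated scenes.
#' @param geom grid geometry of the stacks.
#' @return list(mounds, captures, pedigree, truth); truth carries the
#'   per-female-year covariates, linear predictors and expected counts.
#' @export
generatePopulation <- function(config, seed = 1L, stacks, geom) {
  set.seed(seed)
  nr <- geom$nrow; nc <- geom$ncol
  ## mounds on distinct cells, away from the outermost ring so 3x3 blocks
  ## are complete (the site sits interior to the crop)
  inner <- expand.grid(row = 2L:(nr - 1L), col = 2L:(nc - 1L))
  pick <- inner[sample.int(nrow(inner), config$nMounds), ]
  gps <- cellCenters(as.matrix(pick), geom) +
    matrix(stats::runif(2L * config$nMounds, -12, 12), ncol = 2L)
  theta_rot <- 25 * pi / 180
  Rm <- matrix(c(cos(theta_rot), sin(theta_rot),
                 -sin(theta_rot), cos(theta_rot)), 2L, 2L)
  t_true <- c(-4300, 1250)
  local <- t(solve(Rm, t(sweep(gps, 2L, t_true))))   # inverse similarity
  is_anchor <- seq_len(config$nMounds) <= config$nAnchorMounds
  mounds <- data.frame(
    mound_id = sprintf("M%03d", seq_len(config$nMounds)),
    gps_x = ifelse(is_anchor, gps[, 1L], NA_real_),
    gps_y = ifelse(is_anchor, gps[, 2L], NA_real_),
    local_x = local[, 1L], local_y = local[, 2L],
    row = pick$row, col = pick$col, stringsAsFactors = FALSE)

  years <- config$startYear + seq_len(config$nYears)
  betas <- config$trueBeta
  p_cap <- config$captureProb
  covnames <- c("brightness", "greenness", "wetness", "surface_temperature")
  next_id <- 1L
  new_female <- function(n) {
    ids <- sprintf("F%04d", next_id - 1L + seq_len(n))
    next_id <<- next_id + n
    ids
  }
  pool <- data.frame(female_id = new_female(config$nFemalesPerYear),
                     mound_i = sample.int(config$nMounds,
                                          config$nFemalesPerYear),
                     age = 1L, stringsAsFactors = FALSE)
  caps <- list(); ped <- list(); truth_rows <- list()
  next_off <- 1L
  env_cache <- new.env(parent = emptyenv())
  stk_cache <- .stack_cache(stacks[covnames])
  for (t in years) {
    ## covariates of each female's home range, lag-aligned annual window
    env <- matrix(NA_real_, nrow(pool), 4L,
                  dimnames = list(NULL, covnames))
    for (i in seq_len(nrow(pool))) {
      mi <- pool$mound_i[i]
      key <- paste(mi, t)
      if (is.null(env_cache[[key]])) {
        w <- lagWindow(t, "annual", "offspring")
        cs <- neighborhood3x3(c(mounds$row[mi], mounds$col[mi]), geom)
        env_cache[[key]] <-
          suppressWarnings(.summarize_cached(stk_cache, cellsMatrix(cs), w))
      }
      env[i, ] <- env_cache[[key]][covnames]
    }
    eta <- betas["intercept"] + drop(env %*% betas[covnames])
    npool <- nrow(pool)
    n_off <- stats::rnbinom(npool, mu = exp(eta), size = config$trueTheta)
    p_surv <- stats::plogis(config$survivalLogit)
    m_ids <- mounds$mound_id[pool$mound_i]
    ## adult captures for the breeding pool (thinned)
    capt_f <- stats::runif(npool) <= p_cap["adult"]
    if (any(capt_f))
      caps[[length(caps) + 1L]] <- data.frame(
        individual_id = pool$female_id[capt_f], sex = "F",
        age_class = "adult", year = t, mound_id = m_ids[capt_f],
        date = sprintf("%d-%02d-15", t,
                       sample(c(3L, 8L), sum(capt_f), replace = TRUE)),
        stringsAsFactors = FALSE)
    ## all offspring of the year at once
    M <- sum(n_off)
    off <- data.frame(offspring_id = character(), sex = character(),
                      alive = logical(), stringsAsFactors = FALSE)
    n_surviving <- rep(NA_integer_, npool)
    if (M > 0L) {
      dam_idx <- rep(seq_len(npool), n_off)
      oid <- sprintf("O%05d", next_off - 1L + seq_len(M))
      next_off <- next_off + M
      sex_o <- sample(c("F", "M"), M, replace = TRUE)
      alive_o <- stats::runif(M) <= p_surv
      ped[[length(ped) + 1L]] <- data.frame(
        offspring_id = oid, dam_id = pool$female_id[dam_idx],
        birth_year = t, stringsAsFactors = FALSE)
      capt_o <- stats::runif(M) <= p_cap["juvenile"]
      if (any(capt_o))
        caps[[length(caps) + 1L]] <- data.frame(
          individual_id = oid[capt_o], sex = sex_o[capt_o],
          age_class = "juvenile", year = t, mound_id = m_ids[dam_idx][capt_o],
          date = sprintf("%d-08-15", t), stringsAsFactors = FALSE)
      off <- data.frame(offspring_id = oid, sex = sex_o, alive = alive_o,
                        stringsAsFactors = FALSE)
      surv_by_dam <- tapply(alive_o, factor(dam_idx, levels = seq_len(npool)),
                            sum)
      n_surviving <- ifelse(n_off > 0L, as.integer(surv_by_dam), NA_integer_)
      n_surviving[is.na(n_surviving) & n_off > 0L] <- 0L
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      female_id = pool$female_id, year = t, mound_id = m_ids,
      row = mounds$row[pool$mound_i], col = mounds$col[pool$mound_i],
      brightness = env[, 1L], greenness = env[, 2L],
      wetness = env[, 3L], surface_temperature = env[, 4L],
      eta = unname(eta), mu = unname(exp(eta)),
      n_offspring = n_off, n_surviving = n_surviving,
      stringsAsFactors = FALSE)
    if (t < max(years)) {
      surv <- off[off$alive, , drop = FALSE]
      ## next year's breeding pool: surviving pool adults (up to age 4) plus
      ## every surviving female offspring, topped up with immigrants — so
      ## the adult females captured next year are exactly next year's pool
      keep <- pool[stats::runif(nrow(pool)) <= 0.45 & pool$age < 4L, ,
                   drop = FALSE]
      keep$age <- keep$age + 1L
      fem_surv <- surv$offspring_id[surv$sex == "F"]
      free <- setdiff(seq_len(config$nMounds), keep$mound_i)
      n_add <- min(length(fem_surv), length(free))
      if (n_add > 0L) {
        keep <- rbind(keep, data.frame(
          female_id = fem_surv[seq_len(n_add)],
          mound_i = sample(free, n_add)[seq_len(n_add)], age = 1L,
          stringsAsFactors = FALSE))
      }
      ## surviving offspring not entering the pool (males, overflow females)
      ## are recaptured next year as adults at unclaimed mounds
      rest <- setdiff(surv$offspring_id, keep$female_id)
      if (length(rest)) {
        capt_r <- stats::runif(length(rest)) <= p_cap["adult"]
        if (any(capt_r)) {
          m_r <- mounds$mound_id[sample.int(config$nMounds, sum(capt_r),
                                            replace = TRUE)]
          sex_r <- surv$sex[match(rest[capt_r], surv$offspring_id)]
          caps[[length(caps) + 1L]] <- data.frame(
            individual_id = rest[capt_r], sex = sex_r, age_class = "adult",
            year = t + 1L, mound_id = m_r,
            date = sprintf("%d-03-15", t + 1L), stringsAsFactors = FALSE)
        }
      }
      short <- config$nFemalesPerYear - nrow(keep)
      if (short > 0L) {
        free <- setdiff(seq_len(config$nMounds), keep$mound_i)
        keep <- rbind(keep, data.frame(
          female_id = new_female(short),
          mound_i = sample(free, short), age = 1L, stringsAsFactors = FALSE))
      }
      pool <- keep
    }
  }
  captures <- do.call(rbind, caps)
  pedigree <- if (length(ped)) do.call(rbind, ped) else
    data.frame(offspring_id = character(), dam_id = character(),
               birth_year = integer())
  truth <- do.call(rbind, truth_rows)
  rownames(captures) <- rownames(pedigree) <- rownames(truth) <- NULL
  list(mounds = mounds, captures = captures, pedigree = pedigree,
       truth = truth)
}

#' Generate a daily climate series
#'
#' Daily precipitation with the site's bimodal regime — the July-August
#' monsoon supplying about half the annual total and a weaker
#' December-March winter mode — plus sinusoidal minimum/mean/maximum air
#' temperatures satisfying tmin <= tmean <= tmax every day.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed RNG seed.
#' @return data.frame(date, precip, tmin, tmean, tmax).
#' @export
generateClimate <- function(config, seed = 1L) {
  set.seed(seed)
  d0 <- as.Date(sprintf("%d-07-01", config$startYear))
  d1 <- as.Date(sprintf("%d-06-30", config$startYear + config$nYears))
  dates <- seq(d0, d1, by = "day")
  mo <- as.integer(format(dates, "%m"))
  A <- config$annualPrecip
  rate <- ifelse(mo %in% 7:8, 0.50 * A / 62,
                 ifelse(mo %in% c(12L, 1L, 2L, 3L), 0.30 * A / 121,
                        0.20 * A / 182))
  shape <- 0.6
  precip <- stats::rgamma(length(dates), shape = shape, scale = rate / shape)
  doy <- as.integer(format(dates, "%j"))
  tmean <- 18 + 10 * cos(2 * pi * (doy - .TEMP_PEAK_DOY) / 365.25) +
    stats::rnorm(length(dates), 0, 0.8)
  half_range <- 6 + abs(stats::rnorm(length(dates), 0, 1.5))
  data.frame(date = dates, precip = precip,
             tmin = tmean - half_range, tmean = tmean,
             tmax = tmean + half_range)
}

#' Run the full synthetic study end to end
#'
#' Generates scenes, scales them, builds and z-normalizes the index stacks,
#' generates the population from those stacks (so the offspring model is
#' exactly the one the pipeline assumes), and generates climate. Seeds for
#' the three generators are derived deterministically from `seed`.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed master RNG seed.
#' @param keepScenes keep the (memory-heavy) scene list in the result.
#' @return list(config, seed, stacks, catalog, geom, mounds, captures,
#'   pedigree, climate, truth, and optionally scenes).
#' @export
simulateStudy <- function(config = simConfig(), seed = 1L,
                          keepScenes = FALSE) {
  seed <- as.integer(seed)
  sc <- generateScenes(config, seed = seed)
  scaled <- lapply(sc$scenes, scaleScene)
  stacks <- buildIndexStacks(scaled)
  for (k in c("brightness", "greenness", "wetness"))
    stacks[[k]] <- zTransform(stacks[[k]])
  pop <- generatePopulation(config, seed = seed + 1013L, stacks = stacks,
                            geom = sc$geom)
  climate <- generateClimate(config, seed = seed + 2027L)
  out <- list(config = config, seed = seed, stacks = stacks,
              catalog = sc$catalog, geom = sc$geom,
              mounds = pop$mounds, captures = pop$captures,
              pedigree = pop$pedigree, climate = climate,
              truth = list(scenes = sc$truth, females = pop$truth))
  if (keepScenes) out$scenes <- sc$scenes
  out
}
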