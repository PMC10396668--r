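## Individual- and population-level response variables from capture and
## pedigree tables. Near-exhaustive sampling (98% adult capture probability)
## justifies treating capture as presence.

#' Per-female offspring counts for one year
#'
#' One row per adult female captured in `year`; females with no pedigree
#' offspring that year are included with a count of zero (the pedigree makes
#' true zeros observable). A dam appearing in the pedigree without any
#' capture record raises a referential-integrity warning.
#'
#' @param pedigree data.frame(offspring_id, dam_id, birth_year).
#' @param captures data.frame(individual_id, sex, age_class, year, mound_id,
#'   date).
#' @param year response year t.
#' @return data.frame(female_id, year, n_offspring).
#' @export
offspringCounts <- function(pedigree, captures, year) {
  year <- as.integer(year)
  known <- unique(captures$individual_id)
  orphan_dams <- setdiff(unique(pedigree$dam_id), known)
  if (length(orphan_dams))
    warning(length(orphan_dams), " pedigree dams never captured")
  fem <- unique(captures$individual_id[
    captures$year == year & captures$sex == "F" &
      captures$age_class == "adult"])
  births <- pedigree[pedigree$birth_year == year, , drop = FALSE]
  cnt <- table(factor(births$dam_id, levels = fem))
  data.frame(female_id = fem, year = year,
             n_offspring = as.integer(cnt[fem]),
             stringsAsFactors = FALSE)
}

#' Offspring surviving to age one
#'
#' For females with at least one offspring in year t, counts how many of
#' those offspring were captured in any session of year t+1 (recapture is
#' the observable for survival to reproductive age). Years without t+1
#' capture data yield NA.
#'
#' @param femaleYears output of \code{\link{offspringCounts}}.
#' @param pedigree data.frame(offspring_id, dam_id, birth_year).
#' @param captures capture table.
#' @return `femaleYears` restricted to n_offspring >= 1, with column
#'   n_surviving added.
#' @export
survivingCounts <- function(femaleYears, pedigree, captures) {
  fy <- femaleYears[femaleYears$n_offspring >= 1L, , drop = FALSE]
  fy$n_surviving <- rep(NA_integer_, nrow(fy))
  for (i in seq_len(nrow(fy))) {
    t1 <- fy$year[i] + 1L
    if (!any(captures$year == t1)) next
    off <- pedigree$offspring_id[pedigree$dam_id == fy$female_id[i] &
                                   pedigree$birth_year == fy$year[i]]
    recap <- unique(captures$individual_id[captures$year == t1])
    fy$n_surviving[i] <- sum(off %in% recap)
  }
  rownames(fy) <- NULL
  fy
}

#' Primary mound of a female in one year
#'
#' Modal capture mound; ties broken by earliest capture date, then
#' lexicographic mound id.
#'
#' @param captures capture rows of one female in one year (needs mound_id
#'   and date columns).
#' @return the mound_id.
#' @export
primaryMound <- function(captures) {
  stopifnot(nrow(captures) >= 1L)
  n <- table(captures$mound_id)
  cand <- names(n)[n == max(n)]
  if (length(cand) == 1L) return(cand)
  first <- vapply(cand, function(m)
    min(as.Date(captures$date[captures$mound_id == m])), as.Date(NA))
  cand <- cand[first == min(first)]
  sort(cand)[1L]
}

#' Primary mounds for all female-years
#'
#' @param captures full capture table.
#' @return data.frame(female_id, year, primary_mound) for adult females.
#' @export
primaryMoundTable <- function(captures) {
  fem <- captures[captures$sex == "F" & captures$age_class == "adult", ,
                  drop = FALSE]
  if (nrow(fem) == 0L)
    return(data.frame(female_id = character(), year = integer(),
                      primary_mound = character()))
  sp <- split(fem, paste(fem$individual_id, fem$year, sep = "\r"))
  out <- data.frame(
    female_id = vapply(sp, function(d) d$individual_id[1L], character(1)),
    year = vapply(sp, function(d) d$year[1L], integer(1)),
    primary_mound = vapply(sp, primaryMound, character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$female_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population-level metrics for one year
#'
#' Adult-female counts, offspring totals and per-female means, the number of
#' active mounds (distinct mounds with any resident capture — the
#' population-size proxy), census size (distinct individuals captured), and
#' the change-in-N responses relative to `prevCensus`.
#'
#' @param captures capture table.
#' @param femaleYears per-female rows of \code{\link{offspringCounts}} for
#'   the year, optionally with n_surviving.
#' @param year the year t.
#' @param prevCensus census size in year t-1 (NA for the first year).
#' @return one-row data.frame of PopulationYearMetrics.
#' @export
populationMetrics <- function(captures, femaleYears, year,
                              prevCensus = NA_integer_) {
  year <- as.integer(year)
  cap <- captures[captures$year == year, , drop = FALSE]
  fy <- femaleYears[femaleYears$year == year, , drop = FALSE]
  nfem <- nrow(fy)
  tot <- sum(fy$n_offspring)
  surv_mean <- if ("n_surviving" %in% names(fy) && nfem > 0L)
    mean(fy$n_surviving[fy$n_offspring >= 1L], na.rm = TRUE) else NA_real_
  census <- length(unique(cap$individual_id))
  data.frame(
    year = year,
    n_adult_females = nfem,
    total_offspring = tot,
    mean_offspring_per_female = if (nfem) tot / nfem else NA_real_,
    mean_surviving_per_female = surv_mean,
    n_active_mounds = length(unique(cap$mound_id)),
    census_size = census,
    delta_N = census - prevCensus,
    prop_delta_N = (census - prevCensus) / prevCensus)
}

#' Population metrics across all years
#'
#' @param captures capture table.
#' @param pedigree pedigree table.
#' @return data.frame, one row per capture year, with change-in-N responses
#'   computed against the preceding year (NA in the first year).
#' @export
populationMetricsTable <- function(captures, pedigree) {
  years <- sort(unique(captures$year))
  prev <- NA_integer_
  rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    fy <- offspringCounts(pedigree, captures, years[i])
    fy <- merge(fy,
                survivingCounts(fy, pedigree, captures)[
                  c("female_id", "year", "n_surviving")],
                by = c("female_id", "year"), all.x = TRUE)
    rows[[i]] <- populationMetrics(captures, fy, years[i], prev)
    prev <- rows[[i]]$census_size
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Female-year table: counts, survival and primary mounds
#'
#' Convenience assembly of the individual-fitness response table across all
#' years: per adult female and year, offspring count, surviving-offspring
#' count (NA where undefined) and primary mound.
#'
#' @param captures capture table.
#' @param pedigree pedigree table.
#' @return data.frame(female_id, year, n_offspring, n_surviving,
#'   primary_mound).
#' @export
femaleYearTable <- function(captures, pedigree) {
  years <- sort(unique(captures$year))
  fy <- do.call(rbind, lapply(years, function(y)
    suppressWarnings(offspringCounts(pedigree, captures, y))))
  sv <- do.call(rbind, lapply(split(fy, fy$year), function(d)
    suppressWarnings(survivingCounts(d, pedigree, captures))))
  fy <- merge(fy, sv[c("female_id", "year", "n_surviving")],
              by = c("female_id", "year"), all.x = TRUE)
  pm <- primaryMoundTable(captures)
  fy <- merge(fy, pm, by = c("female_id", "year"), all.x = TRUE)
  fy <- fy[order(fy$year, fy$female_id), , drop = FALSE]
  rownames(fy) <- NULL
  fy
}
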