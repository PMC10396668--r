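---
title: "Linking satellite-derived environment to rodent fitness: models and methods"
author: "kratscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking satellite-derived environment to rodent fitness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Banner-tailed kangaroo rats (*Dipodomys spectabilis*) build large, long-lived
mounds that anchor each animal's home range. In a near-exhaustively trapped
population (twice-yearly sessions, ~98% adult capture probability) with a
genetic pedigree, *individual fitness* is directly observable: the number of
offspring a female produces in a year, and how many of them survive to
reproductive age. This package implements a pipeline that asks which
remotely sensed environmental conditions predict that fitness — and, at the
population scale, which predict mean fitness and population size — when no
contemporaneous ground-based environmental measurements exist.

The environmental measurements are Landsat-5-TM-style multispectral scenes:
six surface-reflectance bands and one thermal band on a 30 m grid, acquired
roughly every few weeks. The reflectance bands are compressed into the three
Tasseled Cap axes (brightness ≈ bare-soil albedo, greenness ≈ photosynthetic
vegetation, wetness ≈ soil/vegetation moisture); the thermal band gives
surface temperature. A daily PRISM-style climate series (precipitation,
tmin/tmean/tmax) serves as the population-scale alternative predictor set.

## Pipeline stages

1. **Scene ingestion** (`readScene`, `cropToExtent`, `scaleScene`,
   `filterSceneSet`). Scenes are stored one plain TIFF per band with an ESRI
   world-file sidecar for georeferencing. Digital numbers are converted with
   the Collection-2 Level-2 affine scalings: reflectance
   $= 0.0000275\,\mathrm{DN} - 0.2$, kelvin
   $= 0.00341802\,\mathrm{DN} + 149$. Scenes from a single WRS path and a
   configured date window are retained; exclusions (e.g. cloud
   contamination) are replayed from a catalog flag with a mandatory reason,
   making the screening step reproducible. Crop extents snap *outward* to
   whole-cell boundaries so a 2100 m × 2750 m request yields a 70 × 92-cell
   grid — a cell intersecting the requested extent is never discarded.
2. **Index computation** (`tasseledCap`, `buildIndexStacks`, `zTransform`).
   Each Tasseled Cap index is a fixed dot product of the six reflectance
   bands using the Crist (1985) reflectance-factor coefficients, transcribed
   into `tasseledCapCoefficients()` and guarded by sign-structure tests.
   Index stacks (cells × scene dates, a `SummarizedExperiment` subclass) are
   pooled-z-transformed: every value is centered and scaled by the mean and
   sample (n − 1) standard deviation over *all* non-masked cells of *all*
   retained scenes. Surface temperature stays in °C. Pooling over the full
   cropped grid of retained scenes is the most literal reading of
   "all cell values across all years"; the normalization parameters are
   stored on the object so it is invertible.
3. **Geolocation** (`fitLocalToMapTransform`, `assignCell`,
   `neighborhood3x3`, `activeLandscape`). Mounds carrying GPS coordinates
   are assigned to cells by the half-open convention (`[edge, edge + 30)` on
   both axes). Mounds mapped only in the site's local meter frame are
   registered through a least-squares similarity transform (closed-form
   orthogonal Procrustes) fitted on the anchor mounds known in both frames —
   an automated, reproducible replacement for what was historically a manual
   overlay, with a CSV override hook for manual corrections and a warning
   when the RMS registration residual exceeds 15 m (half a cell). A female's
   home range is the 3 × 3 cell block around her mound (center to outer
   corner: $45\sqrt{2} \approx 63.6$ m); the active landscape is the
   deduplicated union of such blocks over all female-occupied mounds.
4. **Temporal aggregation** (`lagWindow`, `seasonEqualizedMean`,
   `rainySeasonMean`, `summarizeUnit`, `summarizeClimate`). A six-month lag
   aligns environment to response: offspring produced in year $t$ are
   predicted from July $t-1$ through June $t$; survival of year-$t$
   offspring from July $t$ through June $t+1$ (so survival windows for year
   $t$ equal offspring windows for year $t+1$). Annual summaries are
   *season-equalized*: per-date cell-set means are first averaged within
   each meteorological season (DJF/MAM/JJA/SON), then across seasons, so
   unevenly timed scenes cannot bias the annual covariate. Rainy-season
   summaries are plain means over July–August (summer) or December 1 –
   March 31 (winter; the inclusive March boundary resolves an ambiguous
   "December to March"). Seasons with no scenes are omitted from the outer
   mean with a coverage warning rather than imputed. Daily climate uses the
   same three windows so predictor tables are structurally uniform.
5. **Demography** (`offspringCounts`, `survivingCounts`, `primaryMound`,
   `populationMetrics`). Offspring counts come from the pedigree, with
   zero-offspring females included; survival to age one is operationalized
   as recapture in any session of year $t+1$ — under near-exhaustive
   sampling, recapture is the only observable for survival. The primary
   mound is the modal capture mound (ties: earliest capture date, then
   lexicographic id). "Active" has two senses, both computed: female-occupied
   mounds define landscape cells; any-resident mounds define the
   population-size proxy.
6. **Inference** (`fitCountGlm`, `backwardStepwise`, `likelihoodRatioTest`,
   `gvif`, `fitNbMixed`, `fitLm`, `permutationPvalue`, `predictEffect`).

## The statistical models

Individual fitness is modeled as a log-link count regression,

$$y_i \sim \mathrm{NegBin}(\mu_i, \theta), \qquad
  \log \mu_i = \beta_0 + \beta_B B_i + \beta_G G_i + \beta_W W_i
  + \beta_T T_i,$$

with $B, G, W$ in pooled z-units and $T$ in °C, fitted by maximum likelihood
(`MASS::glm.nb`; Poisson by `stats::glm`). Model selection is backward
stepwise at $p < .05$: the single largest-p predictor is removed per step,
the intercept never; AIC is recorded at every step but never drives removal
(the procedure is p-driven; AIC is logged for inspection). Ties in the
largest p within $10^{-12}$ remove the later column so builds are
deterministic. Diagnostics follow each final fit: a Poisson-vs-NB
likelihood ratio test (df = 1 for $\theta$, reported without boundary
correction to match the conventional practice of the analysis lineage, with
a halved-p boundary option), the Pearson dispersion ratio
$\chi^2/\mathrm{df}$ (reported, never auto-acted on), and determinant-based
GVIF values for multi-predictor models,
$\mathrm{GVIF}_j = \det(R_j)\det(R_{-j})/\det(R)$, which reduces to the
classical $1/(1-r^2)$ for single-column terms.

Because some females contribute several years, an NB mixed model with a
per-female random intercept (glmmTMB, Laplace approximation) is available.
Its convergence reporting is deliberately honest: optimizer failure or an
unreliable Hessian yields `converged = FALSE`, and a random-intercept
standard deviation collapsing to the boundary is flagged `singular` — the
expected outcome when most groups are singletons, as in the survival
setting where 186 of 282 females appear in a single year.

Population-level analyses are single-predictor OLS regressions of each
response (mean offspring per female, mean survivors per female, active
mound count, and the change-in-N responses $N_t - N_{t-1}$ and
$(N_t - N_{t-1})/N_{t-1}$) on each landscape-mean predictor separately.
Because these short yearly series need not satisfy homoskedasticity,
significance uses a permutation null: the response is shuffled `nPerm`
times (default 1000) and the two-sided add-one Monte-Carlo p,
$p = (1 + \#\{|\hat\beta^{(\pi)}| \ge |\hat\beta|\})/(1 + n_\mathrm{perm})$,
is reported. The add-one form guarantees $p > 0$; the permuted statistic is
the slope coefficient (a t-statistic variant differs only by a permutation-
invariant scale factor in the balanced single-predictor case).

Effect displays (`predictEffect`) hold non-focal covariates at their sample
means and show response-scale predictions with Wald 95% intervals.

## The synthetic-data generator

Every stage is testable offline because `simulateStudy()` generates the
whole study with known ground truth, at the study's own dimensions by
default: 13 response years observed by 167 scenes on a 92 × 70 grid of 30 m
cells, 214 mounds (188 with GPS coordinates, the rest only in the local
survey frame under a known similarity transform), and about 37 breeding
females per year (~480 female-years).

* **Surface temperature** follows an annual sinusoid peaking in early July
  (mean 25 °C, amplitude 15 °C — a desert-surface regime with ~10–40 °C
  seasonal range) plus a static spatial field (sd 0.8 °C) and observation
  noise (sd 0.5 °C).
* **Brightness and wetness** are generated as a correlated pair (target
  pooled Pearson r = 0.9, matching the empirically strong coupling of the
  two axes over sparsely vegetated soil), with variance split among a
  static spatial component, a per-scene temporal component and
  cell-by-scene noise; each component carries the same cross-index
  correlation so the pooled correlation hits the target.
* **Greenness** is deliberately weak: low-amplitude noise around a small
  mean, reflecting the near-uninformative greenness signal of semiarid
  grassland at 30 m.
* Index targets are mapped to six band reflectances through the
  Moore–Penrose right inverse of the Tasseled Cap coefficient matrix, so
  the transform of the emitted bands reproduces the targets exactly; DNs
  are quantized to integers so the ingest path is exercised realistically
  (quantization perturbs indices by < 1e-4).
* **Fitness** is drawn from exactly the NB-GLM the inference stage assumes:
  each female-year's covariates are the lag-aligned season-equalized annual
  summaries of her 3 × 3 home range computed from the generated stacks, and
  $y \sim \mathrm{NegBin}(\exp(\beta_0 + x^\top\beta), \theta)$. Defaults
  use the annual-model coefficient scale ($\beta_0 = -0.7191$,
  $\beta_B = 0.359$, $\beta_T = 0.0382$ per °C, other effects zero) and
  $\theta = 2$, a moderate overdispersion consistent with litter-size
  biology (1–2 litters of 1–3 offspring). Offspring survive to the next
  year with logistic probability (default intercept −0.4, survival ≈ 0.40);
  surviving females can join the breeding pool (adults persist with
  probability 0.45 up to age 4, topped up by immigrants), giving the
  repeated-measures structure the mixed models need.
* **Capture records** are emitted for all living animals, thinned by the
  study's capture probabilities (0.98 adults, 0.93 juveniles) by default;
  setting both to 1 makes the demographic bookkeeping round-trip exact,
  which is how the bookkeeping tests are run.
* **Climate** is bimodal: July–August receives ~50% of annual
  precipitation, December–March a secondary mode, with sinusoidal
  temperatures satisfying tmin ≤ tmean ≤ tmax daily.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: cloud and sensor artifacts beyond a fill
sentinel, spatial autocorrelation structure beyond a static Gaussian field,
density dependence, dispersal behavior, misassigned parentage, and
path-to-path radiometric bias (the cross-path diagnostic is exercised on
constructed series instead).

## Numerical and design choices

* Sample (n − 1) denominators everywhere; z-normalization tolerance 1e-9 in
  the stack invariant.
* The degenerate z-transform (zero pooled variance) and undefined Pearson
  correlation (zero variance, < 3 complete pairs) are errors, not NAs.
* Missing covariate rows are dropped listwise with the used n recorded in
  every `ModelResult`.
* `glm.nb`'s theta-iteration warnings on equidispersed data are muffled (the
  NB fit legitimately drifts toward the Poisson limit); genuine failures
  surface as errors or `converged = FALSE`.
* The Poisson boundary case (all-zero counts) warns rather than errors.
* Coefficient-recovery checks assert coverage and bias on the *full*
  four-predictor fit rather than the post-stepwise model: with moderate
  effect sizes, stepwise retention is itself a coin flip near the
  significance boundary and post-selection Wald intervals are not valid
  coverage targets. Stepwise behaviour is validated separately by its
  type-I retention rate under null effects.
* The recovery study uses 100 pipeline replicates at the default study
  dimensions (~480 female-years each); the permutation-null calibration
  uses 500 replicates of n = 50 with 199 permutations each — sizes chosen
  to make Monte-Carlo error small relative to the asserted tolerances.

## Known limitations

* The crop's 2750 m request is not a whole number of 30 m cells; snapping
  outward to 92 rows is a convention, and the original cell count of the
  historical analysis is unrecoverable.
* Whether surface temperature should enter models in K or °C is ambiguous
  in the source material; °C is used (slopes are unaffected, intercepts
  shift by 273.15 × slope).
* Survival-to-age-one by recapture undercounts true survival by the
  (small) adult non-capture probability and cannot distinguish death from
  permanent emigration.
* No atmospheric correction, reprojection, cloud-mask algorithmics, kernel
  home-range estimation, parentage inference or capture-probability
  modeling: coordinates, pedigree and scene quality flags are inputs.
* The NB mixed model's singular-fit flag (random-intercept sd < 1e-3) is a
  pragmatic boundary criterion, not a formal test of zero variance.
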