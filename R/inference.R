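## Model fitting and selection: count GLMs (Poisson / negative binomial) with
## backward stepwise elimination, likelihood-ratio and dispersion/GVIF
## diagnostics, NB mixed models, OLS and permutation-null p-values.

.model_df <- function(y, X) {
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X))
  d <- cbind(data.frame(.y = y), X)
  d[stats::complete.cases(d), , drop = FALSE]
}

.coef_table <- function(sm) {
  cf <- sm
  data.frame(term = rownames(cf), estimate = cf[, 1L], se = cf[, 2L],
             statistic = cf[, 3L], p = cf[, 4L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit a log-link count GLM
#'
#' Poisson by iteratively reweighted least squares, negative binomial by
#' maximum likelihood with theta profiled (MASS::glm.nb, whose AIC charges
#' one parameter for theta). Reports per-term Wald z and p, the Pearson
#' dispersion ratio (chi-square over residual df, reported and never
#' auto-acted on), and per-term GVIF when more than one predictor is
#' present. Rows with missing values are dropped listwise.
#'
#' @param y nonnegative integer response.
#' @param X data.frame (or matrix) of covariates; an intercept is added.
#' @param family "poisson" or "negbin".
#' @return a \linkS4class{ModelResult}.
#' @export
fitCountGlm <- function(y, X = NULL, family = c("poisson", "negbin")) {
  family <- match.arg(family)
  if (any(y < 0, na.rm = TRUE) || any(y != round(y), na.rm = TRUE))
    stop("y must be nonnegative integer counts")
  if (is.null(X) || (!is.null(dim(X)) && ncol(as.data.frame(X)) == 0L))
    X <- data.frame(row.names = seq_along(y))
  d <- .model_df(y, X)
  if (ncol(d) > 1L) {
    mm <- stats::model.matrix(~ ., data = d[-1L])
    if (qr(mm)$rank < ncol(mm))
      stop("singular design: predictors are rank deficient")
  }
  if (all(d$.y == 0L)) warning("all counts are zero: log-link mean at boundary")
  conv <- TRUE
  if (family == "poisson") {
    fit <- stats::glm(.y ~ ., data = d, family = stats::poisson())
    theta <- NA_real_
    conv <- isTRUE(fit$converged)
  } else {
    fit <- withCallingHandlers(
      tryCatch(MASS::glm.nb(.y ~ ., data = d),
               error = function(e) stop("negative binomial fit failed: ",
                                        conditionMessage(e))),
      warning = function(w) {
        ## theta drifting to +Inf on equidispersed data is informative, not
        ## fatal; record and continue
        if (grepl("iteration limit|alternation", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    theta <- fit$theta
    conv <- isTRUE(fit$converged)
  }
  sm <- summary(fit)
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  cf <- .coef_table(sm$coefficients)
  preds <- setdiff(names(d), ".y")
  gv <- if (length(preds) > 1L) gvif(d[preds]) else numeric()
  new("ModelResult", family = family,
      formula = paste(".y ~", paste(c("1", preds), collapse = " + ")),
      coefficients = cf, theta = theta,
      aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
      dispersionRatio = disp, gvif = gv, converged = conv,
      singular = FALSE, n = nrow(d), fit = fit)
}

#' Backward stepwise elimination at a p threshold
#'
#' Refits iteratively, removing the single largest-p predictor while any
#' predictor has p >= alpha; the intercept is never removed. Ties within
#' 1e-12 remove the later column, so builds are deterministic. AIC is
#' recorded at every step but never drives removal.
#'
#' @param y count response.
#' @param X data.frame of candidate predictors (at least one).
#' @param family "poisson" or "negbin".
#' @param alpha significance threshold, default 0.05.
#' @return a \linkS4class{StepwiseTrace}.
#' @export
backwardStepwise <- function(y, X, family = "negbin", alpha = 0.05) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 1L)
  steps <- data.frame(removed_term = character(), p_at_removal = numeric(),
                      aic_after = numeric(), stringsAsFactors = FALSE)
  keep <- names(X)
  fit <- fitCountGlm(y, X[keep], family)
  repeat {
    cf <- coefficientTable(fit)
    cand <- cf[cf$term != "(Intercept)", , drop = FALSE]
    if (nrow(cand) == 0L || max(cand$p) < alpha) break
    worst <- which(cand$p > max(cand$p) - 1e-12)
    drop_term <- cand$term[worst[length(worst)]]   # later column on ties
    keep <- setdiff(keep, drop_term)
    fit <- fitCountGlm(y, if (length(keep)) X[keep] else NULL, family)
    steps <- rbind(steps, data.frame(
      removed_term = drop_term,
      p_at_removal = max(cand$p),
      aic_after = fit@aic, stringsAsFactors = FALSE))
    if (length(keep) == 0L) break
  }
  new("StepwiseTrace", steps = steps, final = fit,
      interceptOnly = length(keep) == 0L)
}

#' Likelihood ratio test between two nested fits
#'
#' 2 * |difference in log-likelihood| against chi-square with df equal to
#' the parameter-count difference. For the Poisson-vs-NB comparison df = 1
#' (theta); `boundary = TRUE` halves the p-value to account for theta being
#' tested at its boundary.
#'
#' @param a,b \linkS4class{ModelResult}s fitted to the same data (same n).
#' @param boundary halve the p-value for a boundary-tested parameter.
#' @return list(statistic, df, p).
#' @export
likelihoodRatioTest <- function(a, b, boundary = FALSE) {
  if (a@n != b@n) stop("models were fitted to different data (n differs)")
  npar <- function(m) nrow(m@coefficients) + !is.na(m@theta) +
    (m@family == "negbin_mixed")
  df <- abs(npar(a) - npar(b))
  if (df == 0L && a@formula != b@formula)
    stop("models are not nested")
  stat <- 2 * abs(a@loglik - b@loglik)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  if (boundary) p <- p / 2
  list(statistic = stat, df = df, p = min(p, 1))
}

#' Generalized variance inflation factors
#'
#' Determinant-based collinearity measure on the predictor correlation
#' matrix: GVIF_j = det(R_j) det(R_-j) / det(R), which reduces to the
#' classical VIF 1/(1 - R_j^2) for single-column terms. Terms may group
#' several columns (e.g. factor dummies).
#'
#' @param X data.frame or matrix of predictor columns (no intercept).
#' @param termGroups optional named list mapping term names to column names;
#'   default one term per column.
#' @return named numeric of GVIF values.
#' @export
gvif <- function(X, termGroups = NULL) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("GVIF needs at least two predictor columns")
  R <- stats::cor(as.matrix(X))
  detR <- det(R)
  if (!is.finite(detR) || detR < 1e-12)
    stop("collinearity error: predictor correlation matrix is singular")
  if (is.null(termGroups))
    termGroups <- setNames(as.list(colnames(X)), colnames(X))
  vapply(termGroups, function(cols) {
    j <- match(cols, colnames(X))
    det(R[j, j, drop = FALSE]) * det(R[-j, -j, drop = FALSE]) / detR
  }, numeric(1))
}

#' Negative binomial mixed model with a random intercept
#'
#' NB GLMM (log link, random intercept per group) via glmmTMB's Laplace
#' approximation. The convergence flag is honest: optimizer failure or an
#' unreliable Hessian gives converged = FALSE, and a random-intercept
#' standard deviation collapsing to the boundary is flagged singular —
#' the expected outcome when most groups are singletons.
#'
#' @param y count response.
#' @param X data.frame of fixed-effect covariates (may be NULL).
#' @param group grouping factor (e.g. female id).
#' @return a \linkS4class{ModelResult} with family "negbin_mixed".
#' @export
fitNbMixed <- function(y, X = NULL, group) {
  if (is.null(X)) X <- data.frame(row.names = seq_along(y))
  d <- cbind(.model_df(y, X), data.frame(.g = factor(group)))
  preds <- setdiff(names(d), c(".y", ".g"))
  fml <- stats::reformulate(c(if (length(preds)) preds else "1", "(1 | .g)"),
                            response = ".y")
  conv <- TRUE
  fit <- tryCatch(
    suppressWarnings(glmmTMB::glmmTMB(fml, data = d,
                                      family = glmmTMB::nbinom2())),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("ModelResult", family = "negbin_mixed",
               formula = deparse(fml), coefficients = data.frame(
                 term = character(), estimate = numeric(), se = numeric(),
                 statistic = numeric(), p = numeric()),
               converged = FALSE, singular = TRUE, n = nrow(d), fit = NULL))
  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  re_sd <- tryCatch(
    sqrt(as.numeric(glmmTMB::VarCorr(fit)$cond$.g[1L, 1L])),
    error = function(e) NA_real_)
  singular <- is.na(re_sd) || re_sd < 1e-3
  sm <- summary(fit)$coefficients$cond
  theta <- tryCatch(glmmTMB::sigma(fit), error = function(e) NA_real_)
  new("ModelResult", family = "negbin_mixed", formula = deparse(fml),
      coefficients = .coef_table(sm),
      theta = if (is.na(theta) || theta <= 0) NA_real_ else theta,
      aic = tryCatch(stats::AIC(fit), error = function(e) NA_real_),
      loglik = as.numeric(stats::logLik(fit)),
      dispersionRatio = NA_real_, gvif = numeric(),
      converged = conv, singular = singular, n = nrow(d), fit = fit)
}

#' Ordinary least squares of y on a single predictor
#'
#' @param y numeric response.
#' @param x numeric predictor.
#' @return a \linkS4class{ModelResult} (family "gaussian"); the underlying
#'   lm is kept for prediction and adjusted R-squared.
#' @export
fitLm <- function(y, x) {
  ok <- stats::complete.cases(y, x)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x[ok]) == 0) stop("singular fit: constant predictor")
  d <- data.frame(.y = y[ok], x = x[ok])
  fit <- stats::lm(.y ~ x, data = d)
  sm <- summary(fit)
  new("ModelResult", family = "gaussian", formula = ".y ~ x",
      coefficients = .coef_table(sm$coefficients),
      aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
      dispersionRatio = NA_real_, converged = TRUE, singular = FALSE,
      n = nrow(d), fit = fit)
}

#' Adjusted R-squared of an OLS ModelResult
#' @param x a \linkS4class{ModelResult} with family "gaussian".
#' @return adjusted R-squared.
#' @export
adjRSquared <- function(x) {
  stopifnot(is(x, "ModelResult"), x@family == "gaussian")
  summary(x@fit)$adj.r.squared
}

#' Permutation p-value for a regression slope
#'
#' Permutes the response `nPerm` times and refits the slope; the two-sided
#' Monte-Carlo p is the add-one estimate
#' (1 + #\{|b_perm| >= |b_obs|\}) / (1 + nPerm), guaranteed positive — the
#' heteroskedasticity-robust alternative to the t-test p.
#'
#' @param y numeric response.
#' @param x numeric predictor.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed recorded in the result.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationPvalue <- function(y, x, nPerm = 1000L, seed = 1L) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  if (stats::var(x) == 0) stop("constant predictor")
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  b_obs <- sum(xc * y) / ssx
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  n <- length(y)
  b_perm <- vapply(seq_len(nPerm), function(i)
    sum(xc * y[sample.int(n)]) / ssx, numeric(1))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p <- (1 + sum(abs(b_perm) >= abs(b_obs))) / (1 + nPerm)
  new("PermutationResult", observed = b_obs, nPerm = as.integer(nPerm),
      p = p, seed = as.integer(seed))
}

#' Predicted response over a focal-covariate grid
#'
#' Response-scale predictions with Wald 95 percent confidence intervals on
#' the link scale, holding every non-focal covariate at its sample mean.
#'
#' @param model a converged \linkS4class{ModelResult} from
#'   \code{\link{fitCountGlm}} or \code{\link{fitLm}}.
#' @param focalTerm name of the focal covariate.
#' @param grid numeric values of the focal covariate.
#' @return data.frame(grid value, fit, lwr, upr) on the response scale.
#' @export
predictEffect <- function(model, focalTerm, grid) {
  if (!isConverged(model)) stop("model did not converge")
  fit <- model@fit
  mf <- fit$model
  vars <- setdiff(names(mf), ".y")
  if (!focalTerm %in% vars)
    stop("focal term '", focalTerm, "' not in the model")
  newd <- as.data.frame(lapply(mf[vars], function(v) mean(v)))
  newd <- newd[rep(1L, length(grid)), , drop = FALSE]
  newd[[focalTerm]] <- grid
  if (inherits(fit, "glm")) {
    pr <- stats::predict(fit, newdata = newd, type = "link", se.fit = TRUE)
    inv <- fit$family$linkinv
  } else {
    pr <- stats::predict(fit, newdata = newd, se.fit = TRUE)
    inv <- identity
  }
  data.frame(x = grid,
             fit = inv(pr$fit),
             lwr = inv(pr$fit - 1.96 * pr$se.fit),
             upr = inv(pr$fit + 1.96 * pr$se.fit),
             row.names = NULL)
}
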