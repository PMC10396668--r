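test_that("count GLMs recover closed-form and simulated truths", {
  ## intercept-only Poisson: MLE of the mean, log link
  m <- fitCountGlm(c(1L, 2L, 3L), family = "poisson")
  expect_equal(coefficientTable(m)$estimate[1], log(2), tolerance = 1e-8)
  expect_equal(modelFamily(m), "poisson")

  expect_warning(fitCountGlm(c(0L, 0L, 0L), family = "poisson"), "boundary")

  ## NB simulation: estimates within 3 standard errors of truth
  set.seed(60)
  n <- 2000L
  x <- rnorm(n)
  mu <- exp(0.5 + 0.3 * x)
  y <- rnbinom(n, mu = mu, size = 2)
  fit <- fitCountGlm(y, data.frame(x = x), "negbin")
  cf <- coefficientTable(fit)
  expect_lt(abs(cf$estimate[1] - 0.5), 3 * cf$se[1])
  expect_lt(abs(cf$estimate[2] - 0.3), 3 * cf$se[2])
  expect_lt(abs(thetaEstimate(fit) - 2), 0.5)
  expect_true(isConverged(fit))
  ## AIC charges theta as a parameter: NB AIC ~ 2*(k+1) - 2*loglik
  expect_equal(fit@aic, 2 * 3 - 2 * fit@loglik, tolerance = 1e-8)

  ## rank-deficient design is refused
  expect_error(fitCountGlm(y, data.frame(x = x, x2 = 2 * x), "poisson"),
               "singular")
})

test_that("NB fit approaches the Poisson fit on equidispersed data", {
  set.seed(61)
  x <- rnorm(1500)
  y <- rpois(1500, exp(0.4 + 0.25 * x))
  po <- fitCountGlm(y, data.frame(x = x), "poisson")
  nb <- fitCountGlm(y, data.frame(x = x), "negbin")
  expect_equal(coefficientTable(nb)$estimate, coefficientTable(po)$estimate,
               tolerance = 1e-4)
  ## dispersion ratio near 1 for a well-specified Poisson model
  expect_equal(dispersionRatio(po), 1, tolerance = 0.15)
})

test_that("backward stepwise removes noise and keeps signal", {
  set.seed(62)
  n <- 500L
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rpois(n, exp(0.3 + 0.5 * x1))      # x2 is pure noise
  tr <- backwardStepwise(y, data.frame(signal = x1, noise = x2),
                         family = "poisson")
  expect_equal(tr@steps$removed_term, "noise")
  expect_equal(coefficientTable(tr@final)$term,
               c("(Intercept)", "signal"))
  expect_false(tr@interceptOnly)

  ## all significant at start: zero steps
  tr2 <- backwardStepwise(y, data.frame(signal = x1), family = "poisson")
  expect_equal(nrow(tr2@steps), 0L)

  ## alpha = 1 keeps the full model; tiny alpha strips to intercept
  tr3 <- backwardStepwise(y, data.frame(signal = x1, noise = x2),
                          family = "poisson", alpha = 1)
  expect_equal(nrow(tr3@steps), 0L)
  tr4 <- backwardStepwise(y, data.frame(signal = x1, noise = x2),
                          family = "poisson", alpha = 1e-300)
  expect_true(tr4@interceptOnly)

  ## two near-copies of one signal: exactly one survives
  set.seed(63)
  xa <- rnorm(n); xb <- xa + rnorm(n, 0, 0.05)
  y2 <- rpois(n, exp(0.3 + 0.4 * xa))
  tr5 <- backwardStepwise(y2, data.frame(a = xa, b = xb),
                          family = "poisson")
  kept <- setdiff(coefficientTable(tr5@final)$term, "(Intercept)")
  expect_equal(length(kept), 1L)
})

test_that("likelihood ratio test separates Poisson from NB when it should", {
  set.seed(64)
  x <- rnorm(800)
  ## strongly overdispersed data: NB wins decisively
  y_od <- rnbinom(800, mu = exp(0.5 + 0.3 * x), size = 0.5)
  po <- fitCountGlm(y_od, data.frame(x = x), "poisson")
  nb <- fitCountGlm(y_od, data.frame(x = x), "negbin")
  lrt <- likelihoodRatioTest(po, nb)
  expect_equal(lrt$df, 1L)
  expect_lt(lrt$p, 1e-10)
  expect_gt(dispersionRatio(po), 1.5)

  ## identical models: statistic 0, p 1
  same <- likelihoodRatioTest(po, po)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  ## equidispersed data: NB is not preferred (small statistic, several seeds)
  for (s in 65:67) {
    set.seed(s)
    yp <- rpois(800, exp(0.4 + 0.2 * x))
    p2 <- fitCountGlm(yp, data.frame(x = x), "poisson")
    n2 <- fitCountGlm(yp, data.frame(x = x), "negbin")
    expect_gt(likelihoodRatioTest(p2, n2)$p, 0.05)
  }

  expect_error(likelihoodRatioTest(po, fitCountGlm(y_od[1:500],
                                                   data.frame(x = x[1:500]),
                                                   "poisson")),
               "different data")
})

test_that("GVIF matches closed forms and flags singular designs", {
  set.seed(68)
  n <- 100L
  ## exactly orthogonal pair (Gram-Schmidt after centering)
  a <- scale(rnorm(n))[, 1]
  b0 <- rnorm(n)
  b0 <- residuals(lm(b0 ~ a))
  b0 <- scale(b0)[, 1]
  g0 <- gvif(data.frame(a = a, b = b0))
  expect_equal(unname(g0), c(1, 1), tolerance = 1e-9)
  ## pair with sample correlation exactly 0.5: VIF = 1/(1 - 0.25) = 4/3
  x2 <- 0.5 * a + sqrt(0.75) * b0
  g <- gvif(data.frame(a = a, x2 = x2))
  expect_equal(unname(g), c(4 / 3, 4 / 3), tolerance = 1e-9)
  ## duplicated predictor is singular
  expect_error(gvif(data.frame(a = a, b = a)), "collinearity")
  ## orthonormal three-column design: all 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  expect_equal(unname(gvif(as.data.frame(q))), rep(1, 3), tolerance = 1e-9)
})

test_that("NB mixed model collapses gracefully with singleton groups", {
  set.seed(69)
  n <- 300L
  x <- rnorm(n)
  y <- rnbinom(n, mu = exp(0.4 + 0.3 * x), size = 2)
  ## all groups singleton: random-effect variance collapses; fixed effects
  ## match the fixed-only model
  mm <- fitNbMixed(y, data.frame(x = x), group = seq_len(n))
  expect_true(isSingular(mm) || !isConverged(mm))
  fix <- fitCountGlm(y, data.frame(x = x), "negbin")
  if (nrow(coefficientTable(mm))) {
    expect_equal(coefficientTable(mm)$estimate,
                 coefficientTable(fix)$estimate, tolerance = 1e-2)
  }
})

test_that("NB mixed model recovers a real grouping variance", {
  set.seed(70)
  g <- rep(1:50, each = 10)
  re <- rnorm(50, 0, 0.5)[g]
  x <- rnorm(500)
  y <- rnbinom(500, mu = exp(0.2 + 0.3 * x + re), size = 3)
  mm <- fitNbMixed(y, data.frame(x = x), group = g)
  expect_true(isConverged(mm))
  expect_false(isSingular(mm))
  re_sd <- sqrt(as.numeric(glmmTMB::VarCorr(mm@fit)$cond$.g[1, 1]))
  ## the model's own Wald interval for the random-effect sd covers the truth
  ci <- suppressMessages(confint(mm@fit))
  sd_row <- grep("Std\\.Dev|\\.g", rownames(ci))[1]
  expect_lt(ci[sd_row, 1], 0.5)
  expect_gt(ci[sd_row, 2], 0.5)
  expect_lt(abs(re_sd - 0.5), 0.25)
  cf <- coefficientTable(mm)
  expect_lt(abs(cf$estimate[cf$term == "x"] - 0.3),
            3 * cf$se[cf$term == "x"])
})

test_that("OLS fits match the normal equations", {
  x <- c(1, 2, 3, 4, 5)
  m <- fitLm(2 * x + 1, x)
  cf <- coefficientTable(m)
  expect_equal(cf$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(adjRSquared(m), 1, tolerance = 1e-10)

  set.seed(71)
  x2 <- rnorm(13); y2 <- rnorm(13)
  m2 <- fitLm(y2, x2)
  X <- cbind(1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(coefficientTable(m2)$estimate, as.vector(beta),
               tolerance = 1e-10)

  ## orthogonalized response: slope exactly zero
  y3 <- residuals(lm(rnorm(13) ~ x2))
  m3 <- fitLm(y3, x2)
  expect_equal(coefficientTable(m3)$estimate[2], 0, tolerance = 1e-10)

  expect_error(fitLm(1:5, rep(2, 5)), "constant")
  expect_error(fitLm(1:2, 1:2), "3 complete")
})

test_that("permutation p-values are exact at the extremes and invariant", {
  x <- rnorm(30)
  ## perfect fit: no permutation beats it, add-one floor
  pr <- permutationPvalue(x, x, nPerm = 999L, seed = 2L)
  expect_equal(pr@p, 1 / 1000)
  ## constant response: slope 0, every permutation ties, p = 1
  pc <- permutationPvalue(rep(3, 30), x, nPerm = 99L, seed = 2L)
  expect_equal(pc@observed, 0)
  expect_equal(pc@p, 1)
  ## invariance under affine rescaling of x and y
  set.seed(72)
  y <- rnorm(30)
  p1 <- permutationPvalue(y, x, nPerm = 199L, seed = 5L)
  p2 <- permutationPvalue(10 * y - 3, 0.5 * x + 7, nPerm = 199L, seed = 5L)
  expect_equal(p1@p, p2@p)
})

test_that("effect predictions hold non-focal covariates at their means", {
  set.seed(73)
  n <- 400L
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- rnbinom(n, mu = exp(0.3 + 0.4 * x1 + 0.2 * x2), size = 2)
  fit <- fitCountGlm(y, data.frame(x1 = x1, x2 = x2), "negbin")
  grid <- c(-1, 0, 1)
  pe <- predictEffect(fit, "x1", grid)
  cf <- coefficientTable(fit)$estimate
  hand <- exp(cf[1] + cf[2] * grid + cf[3] * mean(x2))
  expect_equal(pe$fit, hand, tolerance = 1e-8)
  expect_true(all(pe$lwr <= pe$fit & pe$fit <= pe$upr))
  ## prediction at the covariate means equals the mean-covariate fitted value
  pe0 <- predictEffect(fit, "x1", mean(x1))
  expect_equal(pe0$fit, exp(sum(cf * c(1, mean(x1), mean(x2)))),
               tolerance = 1e-8)
  expect_error(predictEffect(fit, "zz", 0), "not in the model")

  ## intercept-only model predicts a flat line at the fitted mean
  m0 <- fitCountGlm(c(1L, 2L, 3L), family = "poisson")
  expect_error(predictEffect(m0, "x", 0), "not in the model")
})
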