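test_that("partial-likelihood maximizer matches the analytic score-equation root", {
  sd <- SurvivalData(time = c(1, 2, 3), status = c(1, 1, 1))
  fit <- fitCox(sd, cbind(x = c(0, 1, 0)))
  # score equation 1 = u/(u+2) + u/(u+1), u = e^b  =>  u = sqrt(2)
  expect_equal(unname(coef(fit)), 0.5 * log(2), tolerance = 1e-6)
  expect_true(fit@converged)

  # Wald statistic vs a brute-force numerical Hessian at the analytic optimum
  logpl <- function(b) b - log(exp(b) + 2) - log(exp(b) + 1)
  b0 <- 0.5 * log(2)
  h <- 1e-4
  info <- -(logpl(b0 + h) - 2 * logpl(b0) + logpl(b0 - h)) / h^2
  oracleStat <- b0^2 * info
  wt <- waldTest(fit)
  expect_lt(abs(wt$statistic - oracleStat), 1e-6)
  expect_lt(abs(wt$p.value - pchisq(oracleStat, 1, lower.tail = FALSE)), 1e-6)
})

test_that("degenerate designs are refused and the null model has zero-sum residuals", {
  set.seed(41)
  sd <- makeSurvData(30)
  expect_error(fitCox(sd, cbind(const = rep(1, 30))), "constant")
  x <- rnorm(30)
  expect_error(fitCox(sd, cbind(a = x, b = 2 * x)), "collinear")
  nullFit <- fitCox(sd)
  expect_equal(sum(martingaleResiduals(nullFit)), 0, tolerance = 1e-10)
  expect_true(all(martingaleResiduals(nullFit) <= 1 + 1e-12))
  # Breslow baseline of the null model is the Nelson-Aalen estimator
  tt <- survTime(sd); dd <- eventStatus(sd)
  bh <- baselineCumhaz(nullFit)
  na <- cumsum(vapply(bh$time, function(tk)
    sum(dd == 1 & tt == tk) / sum(tt >= tk), 0))
  expect_equal(bh$cumhaz, na, tolerance = 1e-12)
})

test_that("Wald test follows the chi-square(1) formula and guards degenerate variance", {
  mk <- function(cf, v) new("CoxFit", coefficients = c(x = cf),
    vcov = matrix(v, 1, 1, dimnames = list("x", "x")), logLik = 0,
    linearPredictor = numeric(2), baselineCumhaz = data.frame(),
    martingaleResiduals = numeric(2), converged = TRUE, nIter = 1L,
    design = matrix(0, 2, 1), time = c(1, 2), status = c(1, 1),
    ties = "efron")
  expect_equal(waldTest(mk(0, 2))$statistic, 0)
  expect_equal(waldTest(mk(0, 2))$p.value, 1)
  wt <- waldTest(mk(1.96, 1))
  expect_equal(wt$statistic, 3.8416, tolerance = 1e-6)
  expect_equal(wt$p.value, 0.0500, tolerance = 1e-3)
  expect_error(waldTest(mk(1, 0)), "variance")
})

test_that("fitted likelihood improves on the null and tie methods agree without ties", {
  set.seed(42)
  for (i in 1:10) {
    sd <- makeSurvData(60)
    X <- cbind(x = rnorm(60), z = rbinom(60, 1, 0.4))
    fit <- fitCox(sd, X)
    expect_gte(logLik(fit), logLik(fitCox(sd)) - 1e-10)
    fb <- fitCox(sd, X, ties = "breslow")
    expect_lt(max(abs(coef(fit) - coef(fb))), 1e-10)
  }
})

test_that("the estimator recovers a known log-hazard ratio with nominal coverage", {
  set.seed(43)
  reps <- 100
  covered <- logical(reps)
  for (i in seq_len(reps)) {
    n <- 5000
    x <- rnorm(n)
    trueT <- -log(runif(n)) / (0.1 * exp(0.5 * x))
    cens <- rexp(n, rate = 0.11)  # ~50% independent random censoring
    sd <- SurvivalData(time = pmin(trueT, cens),
                       status = as.numeric(trueT <= cens),
                       covariates = cbind(x = x))
    fit <- fitCox(sd, covariates(sd))
    se <- sqrt(vcov(fit)[1, 1])
    covered[i] <- abs(coef(fit)[1] - 0.5) <= qnorm(0.975) * se
  }
  expect_gte(mean(covered), 0.90)
})
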