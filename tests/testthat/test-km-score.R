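test_that("mixture tail matches chi-square closed forms and handles edge cases", {
  expect_equal(daviesPvalue(3.841459, 1)$p, 0.05, tolerance = 1e-5)
  expect_equal(daviesPvalue(5.991465, c(1, 1))$p, exp(-5.991465 / 2),
               tolerance = 1e-4)
  expect_equal(daviesPvalue(0, c(0.5, 2))$p, 1)
  expect_error(daviesPvalue(1, numeric(0)), "eigenvalue")
  # scaled rank-1 mixture is an exactly scaled 1-df tail
  expect_equal(daviesPvalue(7.2, 2.4)$p, pchisq(3, 1, lower.tail = FALSE))
})

test_that("mixture tail agrees with a Monte-Carlo quadratic-form oracle", {
  set.seed(51)
  for (i in 1:20) {
    S <- sample(3:40, 1)
    lam <- sort(rexp(S), decreasing = TRUE)
    q <- sum(lam) * runif(1, 0.5, 3)
    p <- daviesPvalue(q, lam)$p
    mc <- mcMixtureTail(q, lam)
    expect_lt(abs(p - mc$p), 3 * mc$se + 1e-4)
  }
})

test_that("Liu moment approximation tracks the exact tail", {
  set.seed(52)
  lam <- sort(rexp(15), decreasing = TRUE)
  for (q in sum(lam) * c(1, 1.5, 2.5)) {
    expect_equal(iehc:::.liuTail(q, lam), daviesPvalue(q, lam)$p,
                 tolerance = 0.05)
  }
})

test_that("kernel score statistic reduces correctly in degenerate and rank-1 cases", {
  set.seed(53)
  sd <- makeSurvData(120)
  nullFit <- fitCox(sd, covariates(sd))
  r <- martingaleResiduals(nullFit)
  G0 <- matrix(0, 120, 4)
  res0 <- kmScoreTest(nullFit, G0)
  expect_equal(scoreStatistic(res0), 0)
  expect_equal(pValue(res0), 1)
  expect_identical(tailMethod(res0), "degenerate")

  g <- rbinom(120, 2, 0.3)
  res1 <- kmScoreTest(nullFit, matrix(g, ncol = 1))
  expect_equal(scoreStatistic(res1), sum(g * r)^2, tolerance = 1e-10)
  lam <- nullEigenvalues(res1)
  expect_length(lam, 1L)
  expect_equal(pValue(res1),
               pchisq(scoreStatistic(res1) / lam, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  expect_error(kmScoreTest(nullFit, matrix(0, 10, 2)), "alignment")
})

test_that("eigenvalue mass is conserved and the analytic p matches simulation from its null", {
  set.seed(54)
  n <- 300; S <- 35
  G <- simulateGenotypes(n, S, runif(S, 0.1, 0.5), ldRho = 0.5)
  sd <- makeSurvData(n, censorRate = 0.5)
  nullFit <- fitCox(sd, covariates(sd))
  res <- kmScoreTest(nullFit, G)
  fac <- iehc:::.coxInfoFactors(nullFit)
  M <- iehc:::.coxInfoProduct(fac, G, G)
  X <- covariates(sd)
  GVX <- iehc:::.coxInfoProduct(fac, G, X)
  XVX <- iehc:::.coxInfoProduct(fac, X, X)
  M <- M - GVX %*% solve(XVX, t(GVX))
  expect_equal(sum(nullEigenvalues(res)), sum(diag(M)), tolerance = 1e-6)

  mc <- mcMixtureTail(scoreStatistic(res), nullEigenvalues(res), nDraw = 1e5)
  expect_lt(abs(pValue(res) - mc$p), 3 * mc$se + 1e-4)
})

test_that("variance-component p-values are uniform under the null", {
  set.seed(55)
  reps <- 300
  pv <- numeric(reps)
  for (i in seq_len(reps)) {
    G <- matrix(rbinom(150 * 10, 2, 0.3), 150, 10)
    sd <- makeSurvData(150, censorRate = 0.5)
    pv[i] <- pValue(kmScoreTest(fitCox(sd, covariates(sd)), G))
  }
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})
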