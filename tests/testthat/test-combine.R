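test_that("Fisher combination equals the 4-df closed form", {
  expect_equal(fisherCombine(1, 1), 1)
  expect_equal(fisherCombine(0.05, 0.05), 0.01748, tolerance = 1e-3)
  expect_equal(fisherCombine(0.5, 0.5), 0.5966, tolerance = 1e-3)
  for (p1 in c(0.001, 0.05, 0.3, 0.9)) for (p2 in c(0.01, 0.4, 1)) {
    T <- -2 * (log(p1) + log(p2))
    expect_equal(fisherCombine(p1, p2), exp(-T / 2) * (1 + T / 2),
                 tolerance = 1e-12)
  }
  expect_warning(fisherCombine(0, 0.5), "clamp")
})

test_that("adaptive combination is symmetric, exact at the boundary, and matches its Monte-Carlo null", {
  expect_equal(adaptCombine(1, 1), 1)
  for (p1 in c(0.02, 0.17, 0.6)) for (p2 in c(0.04, 0.5, 0.95)) {
    expect_identical(adaptCombine(p1, p2), adaptCombine(p2, p1))
  }
  set.seed(61)
  N <- 1e7
  u <- runif(N); v <- runif(N)
  Tuv <- -2 * (log(u) + log(v))
  mm <- pmin(u, v, exp(-Tuv / 2) * (1 + Tuv / 2))
  for (pp in list(c(0.05, 0.5), c(0.05, 0.05), c(0.001, 0.9))) {
    obs <- min(pp, fisherCombine(pp[1], pp[2]))
    pmc <- mean(mm <= obs)
    se <- sqrt(pmc * (1 - pmc) / N)
    expect_lt(abs(adaptCombine(pp[1], pp[2]) - pmc), 3 * se + 1e-6)
  }
})

test_that("optimal combination reduces to its components at single-point grids", {
  set.seed(62)
  sd <- makeSurvData(200, censorRate = 0.5)
  G <- matrix(rbinom(200 * 8, 2, 0.25), 200, 8)
  s <- G %*% rnorm(8)
  fit <- fitCox(sd, cbind(burden = as.vector(s), covariates(sd)))
  km <- kmScoreTest(fit, G)
  uTheta <- waldTest(fit, 1)$statistic
  pTheta <- waldTest(fit, 1)$p.value
  expect_equal(optimCombine(uTheta, km, rhoGrid = 1)$p, pTheta,
               tolerance = 1e-6)
  expect_equal(optimCombine(uTheta, km, rhoGrid = 0)$p, pValue(km),
               tolerance = 1e-9)
  expect_error(optimCombine(uTheta, km, rhoGrid = numeric(0)), "empty")
})

test_that("optimal combination calibration matches a Monte-Carlo min-p oracle", {
  set.seed(63)
  grid <- c(0, 0.0625, 0.25, 0.5625, 1)
  N <- 1e6
  for (case in 1:2) {
    S <- sample(8:25, 1)
    lam <- sort(rexp(S), decreasing = TRUE)
    km <- new("KernelScoreResult", Q = sum(lam) * runif(1, 1, 2.5),
              eigenvalues = lam, pValue = 0.5, tailMethod = "davies")
    uTheta <- rchisq(1, 1) + 1
    res <- optimCombine(uTheta, km, rhoGrid = grid)
    # oracle: P(min_rho p_rho <= observed) via the per-rho quantiles at minP
    qR <- vapply(grid, function(r) {
      e <- c(r, (1 - r) * lam); e <- e[e > 1e-12 * max(e)]
      iehc:::.mixtureQuantile(res$minP, e)
    }, 0)
    Uth <- rchisq(N, 1)
    Uta <- colSums(lam * matrix(rchisq(S * N, 1), S))
    rej <- rep(FALSE, N)
    for (k in seq_along(grid))
      rej <- rej | (grid[k] * Uth + (1 - grid[k]) * Uta >= qR[k])
    pmc <- mean(rej)
    se <- sqrt(pmc * (1 - pmc) / N)
    expect_lt(abs(res$p - pmc), 3 * se + 1e-4)
  }
})

test_that("Cauchy combination obeys its identities and the worked example", {
  expect_equal(acatCombine(rep(0.5, 4)), 0.5, tolerance = 1e-12)
  for (p in c(0.001, 0.05, 0.3, 0.77)) {
    expect_equal(acatCombine(rep(p, 5)), p, tolerance = 1e-10)
  }
  expect_lt(abs(acatCombine(c(0.01, 0.5)) - 0.0200), 5e-4)
  expect_error(acatCombine(numeric(0)), "empty")
  expect_error(acatCombine(c(0.1, 0.2), weights = c(0, 0)), "weights")
  # tiny p handled through the tangent asymptote
  expect_lt(acatCombine(c(1e-20, 0.5)), 1e-18)
})

test_that("each combiner is monotone in its inputs", {
  grid <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  for (f in list(fisherCombine, adaptCombine,
                 function(a, b) acatCombine(c(a, b)))) {
    for (b in grid) {
      vals <- vapply(grid, function(a) f(a, b), 0)
      expect_true(all(diff(vals) >= -1e-12))
    }
  }
})
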