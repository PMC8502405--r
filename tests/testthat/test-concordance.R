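test_that("gene regression matches the normal-equation oracle and its identities", {
  set.seed(91)
  x <- rnorm(12); y <- 1.3 + 0.7 * x + rnorm(12, sd = 0.4)
  res <- geneRegression(y, x, gene = "g")
  xc <- x - mean(x); yc <- y - mean(y)
  slope <- sum(xc * yc) / sum(xc^2)
  expect_equal(res$slope, slope, tolerance = 1e-10)
  expect_equal(res$r2, cor(x, y)^2, tolerance = 1e-10)

  exact <- suppressWarnings(geneRegression(2 * x, x))
  expect_equal(exact$slope, 2, tolerance = 1e-10)
  expect_equal(exact$r2, 1, tolerance = 1e-10)
  expect_lt(exact$p, 1e-12)

  resid <- lm(y ~ x)$residuals
  orth <- geneRegression(resid, x)
  expect_equal(orth$slope, 0, tolerance = 1e-10)
  expect_equal(orth$r2, 0, tolerance = 1e-10)

  expect_identical(geneRegression(y[1:2], x[1:2])$flag, "too_few_snps")
  expect_identical(geneRegression(y, rep(1, 12))$flag, "zero_variance_covariate")
})

test_that("marginal Cox effects recover a known SNP effect and flag degenerate SNPs", {
  set.seed(92)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  sd <- makeSurvData(n, eta = 0.3 * g, censorRate = 0.4)
  G <- cbind(causal = g, mono = rep(1, n) * 0)
  est <- suppressMessages(marginalCoxEffects(G, sd))
  expect_true(is.na(est["mono"]))
  fit <- fitCox(sd, cbind(g = g, covariates(sd)))
  se <- sqrt(vcov(fit)[1, 1])
  expect_lt(abs(est["causal"] - 0.3), qnorm(0.975) * se * 1.5)
})

test_that("enrichment chi-square uses the continuity correction and rate ratio", {
  ident <- enrichmentTest(10, 90, 10, 90)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)
  expect_equal(ident$rateRatio, 1)

  hand <- enrichmentTest(20, 80, 10, 90)
  expect_equal(hand$statistic, 3.18, tolerance = 1e-2)
  expect_equal(hand$p.value, 0.0747, tolerance = 1e-3)
  expect_equal(hand$rateRatio, 2)

  sw <- enrichmentTest(10, 90, 20, 80)
  expect_equal(sw$statistic, hand$statistic)
  expect_equal(sw$p.value, hand$p.value)
  expect_equal(sw$rateRatio, 1 / hand$rateRatio, tolerance = 1e-12)

  expect_error(enrichmentTest(0, 0, 5, 5), "margin")
  expect_error(enrichmentTest(-1, 2, 3, 4), "nonnegative")
})

test_that("null concordance study yields (almost) no FDR discoveries", {
  set.seed(93)
  nGene <- 25
  rows <- lapply(seq_len(nGene), function(g) {
    S <- sample(8:15, 1)
    data.frame(gene = paste0("g", g),
               surv_effect = rnorm(S, sd = 0.1),
               eqtl_effect = rnorm(S))
  })
  tab <- concordanceTable(do.call(rbind, rows))
  expect_equal(nrow(tab), nGene)
  expect_true(all(tab$q >= tab$p, na.rm = TRUE))
  expect_lte(sum(tab$q < 0.05, na.rm = TRUE), 2)
})
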