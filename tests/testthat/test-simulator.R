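test_that("replicates are deterministic in the seed and structurally valid", {
  set.seed(81); r1 <- simulateReplicate(simConfig())
  set.seed(81); r2 <- simulateReplicate(simConfig())
  expect_identical(r1$alpha, r2$alpha)
  expect_identical(dosages(r1$G2), dosages(r2$G2))
  expect_identical(survTime(r1$pheno), survTime(r2$pheno))
  expect_true(all(dosages(r1$G2) %in% 0:2))
  expect_true(all(r1$G1 %in% 0:2))
  expect_true(all(survTime(r1$pheno) > 0))
  expect_true(all(eventStatus(r1$pheno) %in% 0:1))
  expect_length(r1$alpha, r1$S)
})

test_that("genotype generator hits target frequencies and LD structure", {
  set.seed(82)
  G <- simulateGenotypes(5000, 6, maf = 0.3, ldRho = 0.5)
  expect_lt(max(abs(colMeans(G) / 2 - 0.3)), 0.02)
  G0 <- simulateGenotypes(2000, 10, maf = 0.25, ldRho = 0)
  cc <- cor(G0)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)
  # AR(1) latent correlation induces decaying dosage correlation
  G5 <- simulateGenotypes(4000, 10, maf = 0.25, ldRho = 0.7)
  c5 <- cor(G5)
  adj <- mean(c5[cbind(1:9, 2:10)])
  far <- mean(c5[cbind(1:5, 6:10)])
  expect_gt(adj, 0.3)
  expect_gt(adj, far + 0.1)
  expect_error(simulateGenotypes(10, 2, maf = 0.7), "maf")
})

test_that("eQTL generator zeroes the exact SNP count and hits the PVE target", {
  set.seed(83)
  G1 <- simulateGenotypes(165, 40, runif(40, 0.05, 0.5), 0.5)
  eq <- simulateEqtl(G1, pve = 0.3, propZero = 0.5)
  expect_equal(sum(eq$beta == 0), 20L)
  # pve -> 0 limit: pure noise
  eq0 <- simulateEqtl(G1, pve = 0, propZero = 0)
  expect_true(all(eq0$beta == 0))

  pves <- replicate(100, {
    S <- sample(20:50, 1)
    G <- simulateGenotypes(165, S, runif(S, 0.05, 0.5), 0.5)
    e <- simulateEqtl(G, pve = 0.3, propZero = 0.3)
    gen <- as.vector(G %*% e$beta)
    var(gen) / var(e$expression)
  })
  expect_lt(abs(mean(pves) - 0.3), 0.02)
})

test_that("survival generator honors the Weibull law and the exact censoring count", {
  set.seed(84)
  G2 <- simulateGenotypes(300, 5, 0.3, 0.5)
  sv <- simulateSurvival(G2, alpha = rep(0, 5), censorRate = 0.5)
  expect_equal(sum(sv$status == 0), 150L)
  expect_true(all(sv$time[sv$status == 0] < sv$trueTime[sv$status == 0]))
  sv0 <- simulateSurvival(G2, alpha = rep(0, 5), censorRate = 0)
  expect_true(all(sv0$status == 1))
  expect_identical(sv0$time, sv0$trueTime)
  # eta = 0, shape 1: exponential(0.01), median log(2)/0.01
  Gz <- matrix(0, 20000, 1)
  svz <- simulateSurvival(Gz, alpha = 0, covariateEffects = c(0, 0),
                          censorRate = 0)
  expect_equal(median(svz$trueTime), log(2) / 0.01, tolerance = 0.05)
})

test_that("hierarchical effects reconstruct the direct-effect variance", {
  set.seed(85)
  cfg <- simConfig(theta = 0.3, tau = 0.04)
  b <- unlist(replicate(150, simulateReplicate(cfg)$b, simplify = FALSE))
  expect_lt(abs(var(b) - 0.04), 3 * 0.04 * sqrt(2 / length(b)) + 0.002)
  r <- simulateReplicate(cfg)
  expect_equal(r$alpha - r$beta * 0.3, r$b, tolerance = 1e-12)
})

test_that("calibration runner is reproducible and refuses tiny runs", {
  expect_error(runNullCalibration(reps = 50), "100")
  expect_error(runNullCalibration(simConfig(theta = 0.1), reps = 100), "null")
  c1 <- runNullCalibration(reps = 100, seed = 9, tests = "components")
  c2 <- runNullCalibration(reps = 100, seed = 9, tests = "components")
  expect_identical(c1$results, c2$results)
  expect_identical(c1$independence$estimate, c2$independence$estimate)
})
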