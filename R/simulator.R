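#' Simulation configuration
#'
#' Default values reproduce the generative protocol of the calibration and
#' power experiments: a 165-subject expression cohort and a disjoint
#' 300-subject survival cohort drawn over the same SNPs; the SNP count per
#' gene uniform on 20..50 (mean 35); gene expression with a target
#' proportion of variance explained (PVE) of 0.3; a fraction of SNPs with
#' exactly zero eQTL effect; SNP effects on survival
#' \eqn{\alpha = \beta\theta + b} with \eqn{b \sim N(0, \tau)}; two
#' covariates (binary and standard normal) each with effect 0.5; Weibull
#' survival times with shape 1 and scale 0.01; and 50\% random censoring.
#' Per-SNP MAFs are uniform on (0.05, 0.5) and the latent AR(1) LD
#' correlation is 0.5 (the synthetic stand-in for correlated nearby SNPs).
#'
#' @param nExpr expression-cohort size.
#' @param nSurv survival-cohort size.
#' @param sRange inclusive integer range the per-gene SNP count is drawn
#'   from.
#' @param mafRange per-SNP MAF interval.
#' @param ldRho AR(1) latent correlation between adjacent SNPs.
#' @param pve target expression PVE in (0, 1), or 0 for pure noise.
#' @param propZero fraction of SNPs forced to zero eQTL effect.
#' @param theta eQTL-score (burden) effect on the log hazard.
#' @param tau variance of the direct per-SNP effects.
#' @param covariateEffects log-hazard effects of the two covariates.
#' @param weibullShape,weibullScale Weibull survival parameters.
#' @param censorRate fraction of subjects randomly censored.
#' @return list of class `sim_config`.
#' @export
simConfig <- function(nExpr = 165L, nSurv = 300L, sRange = c(20L, 50L),
                      mafRange = c(0.05, 0.5), ldRho = 0.5, pve = 0.3,
                      propZero = 0.3, theta = 0, tau = 0,
                      covariateEffects = c(0.5, 0.5), weibullShape = 1,
                      weibullScale = 0.01, censorRate = 0.5) {
  stopifnot(pve >= 0, pve < 1, tau >= 0, censorRate >= 0, censorRate < 1,
            weibullShape > 0, weibullScale > 0, propZero >= 0, propZero <= 1,
            ldRho >= 0, ldRho < 1, sRange[1] >= 1, sRange[2] >= sRange[1],
            all(mafRange > 0), all(mafRange <= 0.5))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate LD-structured genotype dosages
#'
#' Two independent latent Gaussian haplotype vectors per subject with AR(1)
#' correlation `ldRho^|j-k|` between SNPs j and k; each haplotype carries the
#' effect allele where its latent value exceeds the upper-MAF normal
#' quantile, and the dosage is the sum of the two haplotypes, giving
#' Hardy-Weinberg genotypes at the target frequencies with controllable
#' local LD.
#'
#' @param n subjects.
#' @param S SNPs.
#' @param maf per-SNP effect-allele frequency in (0, 0.5], length 1 or S.
#' @param ldRho AR(1) latent correlation in \[0, 1).
#' @return n x S dosage matrix with entries 0/1/2.
#' @export
simulateGenotypes <- function(n, S, maf, ldRho = 0.5) {
  maf <- rep_len(maf, S)
  if (any(maf <= 0 | maf > 0.5)) stop("maf entries must lie in (0, 0.5]")
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must lie in [0, 1)")
  thresh <- stats::qnorm(1 - maf)
  hap <- function() {
    Z <- matrix(stats::rnorm(n * S), n, S)
    if (ldRho > 0 && S > 1) {
      for (j in 2:S) Z[, j] <- ldRho * Z[, j - 1] + sqrt(1 - ldRho^2) * Z[, j]
    }
    sweep(Z, 2, thresh, ">") * 1
  }
  d <- hap() + hap()
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("snp", seq_len(S)))
  d
}

#' Simulate eQTL effects and gene expression at a target PVE
#'
#' Draws standard-normal effect sizes, forces a `propZero` fraction of them
#' (exactly `round(propZero * S)` SNPs) to zero, then rescales so that the
#' empirical variance of the genetic component \eqn{G_1\beta} equals
#' `pve/(1-pve)` times the unit residual variance; expression is the genetic
#' component plus standard-normal noise, so the realized PVE fluctuates
#' around the target through the realized residual variance.  Rescaling is
#' per replicate (empirical), so small SNP sets still hit the target.
#'
#' @param G1 expression-cohort dosage matrix.
#' @param pve target PVE in \[0, 1).
#' @param propZero fraction of SNPs with zero effect.
#' @return list with `beta` and `expression`.
#' @export
simulateEqtl <- function(G1, pve, propZero = 0) {
  S <- ncol(G1)
  for (try in 1:100) {
    beta <- stats::rnorm(S)
    nZero <- round(propZero * S)
    if (nZero > 0) beta[sample.int(S, nZero)] <- 0
    g <- as.vector(G1 %*% beta)
    vg <- stats::var(g)
    if (pve == 0) { beta <- beta * 0; g <- g * 0; break }
    if (vg > 0) {
      beta <- beta * sqrt((pve / (1 - pve)) / vg)
      g <- as.vector(G1 %*% beta)
      break
    }
    if (try == 100) stop("could not draw a non-degenerate effect vector")
    message("all-zero genetic component; re-drawing effect sizes")
  }
  list(beta = beta, expression = g + stats::rnorm(nrow(G1)))
}

#' Simulate Weibull survival with random censoring
#'
#' Inverse-probability draw of the true time
#' \eqn{T = (-\log U / (\mathrm{scale}\, e^\eta))^{1/\mathrm{shape}}} with
#' \eqn{\eta = G_2\alpha + c_1 X_1 + c_2 X_2}, \eqn{X_1 \sim} Bernoulli(0.5)
#' and \eqn{X_2 \sim N(0,1)}.  Exactly `floor(censorRate * n)` randomly
#' chosen subjects are censored at a uniform fraction of their true time
#' (censoring independent of covariates, marginal rate preserved exactly);
#' the rest are observed events.
#'
#' @param G2 survival-cohort dosage matrix.
#' @param alpha per-SNP total log-hazard effects.
#' @param covariateEffects length-2 effects of the binary and continuous
#'   covariate.
#' @param shape,scale Weibull parameters.
#' @param censorRate fraction censored in \[0, 1).
#' @return list with `time`, `status`, `X1`, `X2`, `trueTime`.
#' @export
simulateSurvival <- function(G2, alpha, covariateEffects = c(0.5, 0.5),
                             shape = 1, scale = 0.01, censorRate = 0.5) {
  stopifnot(shape > 0, scale > 0, censorRate >= 0, censorRate < 1)
  n <- nrow(G2)
  X1 <- stats::rbinom(n, 1, 0.5)
  X2 <- stats::rnorm(n)
  eta <- as.vector(G2 %*% alpha) + covariateEffects[1] * X1 +
    covariateEffects[2] * X2
  U <- stats::runif(n)
  trueTime <- (-log(U) / (scale * exp(eta)))^(1 / shape)
  status <- rep(1, n)
  time <- trueTime
  nCens <- floor(censorRate * n)
  if (nCens > 0) {
    idx <- sample.int(n, nCens)
    status[idx] <- 0
    time[idx] <- stats::runif(nCens) * trueTime[idx]
  }
  list(time = time, status = status, X1 = X1, X2 = X2, trueTime = trueTime)
}

# Marginal per-SNP simple-regression eQTL estimates (one SNP at a time, with
# intercept), vectorized; monomorphic SNPs get weight 0.
.marginalEqtl <- function(G1, y) {
  gc <- sweep(G1, 2, colMeans(G1))
  yc <- y - mean(y)
  ss <- colSums(gc^2)
  b <- as.vector(crossprod(gc, yc)) / ss
  b[ss == 0] <- 0
  b
}

#' Simulate one complete replicate of the study
#'
#' Draws the SNP count and MAFs, the disjoint expression and survival
#' cohorts over the same SNPs, eQTL effects and expression, the hierarchical
#' SNP effects \eqn{\alpha = \beta\theta + b}, and the survival outcome.
#' The weights handed to the association tests are, by default, the marginal
#' per-SNP eQTL estimates from the expression cohort (mirroring the use of
#' external marginal summary statistics); `weightType = "true"` uses the
#' generative \eqn{\beta} instead.
#'
#' @param config a [simConfig()] list.
#' @param weightType `"marginal"` or `"true"`.
#' @return list with `G1`, `G2` ([GenotypeMatrix-class]), `beta`,
#'   `expression`, `b`, `alpha`, `weights`, `pheno`
#'   ([SurvivalData-class] with the two covariates), `S`.
#' @export
simulateReplicate <- function(config = simConfig(),
                              weightType = c("marginal", "true")) {
  weightType <- match.arg(weightType)
  S <- sample(seq(config$sRange[1], config$sRange[2]), 1L)
  maf <- stats::runif(S, config$mafRange[1], config$mafRange[2])
  G1 <- simulateGenotypes(config$nExpr, S, maf, config$ldRho)
  G2 <- simulateGenotypes(config$nSurv, S, maf, config$ldRho)
  eq <- simulateEqtl(G1, config$pve, config$propZero)
  b <- stats::rnorm(S, 0, sqrt(config$tau))
  alpha <- eq$beta * config$theta + b
  sv <- simulateSurvival(G2, alpha, config$covariateEffects,
                         config$weibullShape, config$weibullScale,
                         config$censorRate)
  weights <- if (weightType == "marginal") .marginalEqtl(G1, eq$expression)
             else eq$beta
  pheno <- SurvivalData(time = sv$time, status = sv$status,
                        covariates = cbind(X1 = sv$X1, X2 = sv$X2),
                        subjectId = rownames(G2))
  list(G1 = G1,
       G2 = GenotypeMatrix(G2,
                           effectAllele = rep("A", S),
                           otherAllele = rep("G", S)),
       beta = eq$beta, expression = eq$expression, b = b, alpha = alpha,
       weights = weights, pheno = pheno, S = S)
}

# Deterministic per-replicate child seed, kept below 2^31.
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483629)
}

.runReplicate <- function(config, tests, rhoGrid) {
  rep <- simulateReplicate(config)
  iehcTest(rep$G2, rep$weights, rep$pheno, rhoGrid = rhoGrid, tests = tests)
}

#' Null calibration: type I error, p uniformity, statistic independence
#'
#' Runs seeded null replicates (theta = 0, tau = 0) and reports per-test
#' rejection rates at the requested levels with binomial standard errors,
#' Kolmogorov-Smirnov uniformity p-values, and the Pearson correlation
#' between the burden statistic \eqn{U_\theta} and the decorrelated
#' variance-component statistic \eqn{U_\tau} with its confidence interval.
#' With `tests = "components"` only the two component statistics are
#' computed (sufficient for the independence experiment, and much faster).
#'
#' @param config a [simConfig()] with theta = 0 and tau = 0.
#' @param reps number of replicates (at least 100; fewer is refused as
#'   meaningless calibration).
#' @param alpha rejection levels to tabulate.
#' @param seed integer seed; every replicate derives a child seed from it.
#' @param tests `"all"` or `"components"`.
#' @param rhoGrid grid for the optimal combination.
#' @return list with `results` (per-replicate data.frame), `rejection`
#'   (level x test table), `uniformityKS`, `independence`
#'   (estimate, CI, p), `reps`, `seed`.
#' @export
runNullCalibration <- function(config = simConfig(), reps = 2000L,
                               alpha = c(0.05, 0.01), seed = 1L,
                               tests = c("all", "components"),
                               rhoGrid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1)) {
  tests <- match.arg(tests)
  if (reps < 100L) stop("fewer than 100 replicates is not a calibration")
  if (config$theta != 0 || config$tau != 0)
    stop("null calibration requires theta = 0 and tau = 0")
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    set.seed(.childSeed(seed, i))
    r <- .runReplicate(config, tests, rhoGrid)
    rows[[i]] <- data.frame(rep = i, uTheta = r$uTheta, uTau = r$uTau,
                            p_burden = r$pBurden, p_tau_decor = r$pTauDecor,
                            p_km = r$pKm, p_fisher = r$pFisher,
                            p_adapt = r$pAdapt, p_optim = r$pOptim,
                            p_acat = r$pAcat)
  }
  res <- do.call(rbind, rows)
  testCols <- if (tests == "all")
    c("p_burden", "p_km", "p_fisher", "p_adapt", "p_optim", "p_acat")
  else c("p_burden", "p_tau_decor")
  rejection <- do.call(rbind, lapply(alpha, function(a) {
    rates <- vapply(testCols, function(cn) mean(res[[cn]] <= a, na.rm = TRUE), 0)
    data.frame(alpha = a, test = sub("p_", "", testCols), rate = rates,
               se = sqrt(rates * (1 - rates) / reps), row.names = NULL)
  }))
  uniformityKS <- vapply(testCols, function(cn)
    suppressWarnings(stats::ks.test(res[[cn]], "punif")$p.value), 0)
  ct <- stats::cor.test(res$uTheta, res$uTau)
  list(results = res, rejection = rejection, uniformityKS = uniformityKS,
       independence = list(estimate = unname(ct$estimate),
                           conf.int = as.numeric(ct$conf.int),
                           p.value = ct$p.value),
       reps = reps, seed = seed)
}

#' Power grid over (theta, tau)
#'
#' Per-cell, per-test rejection proportions at level `alpha` with
#' Monte-Carlo standard errors.  Replicate i uses the same child seed in
#' every cell, so power is comparable (and monotone in effect size up to MC
#' error) across cells.
#'
#' @param config base [simConfig()]; theta/tau are overridden per cell.
#' @param thetaGrid,tauGrid effect grids; the (0, 0) cell is skipped.
#' @param reps replicates per cell (at least 100).
#' @param alpha rejection level.
#' @param seed integer seed.
#' @param rhoGrid grid for the optimal combination.
#' @return data.frame with theta, tau, test, power, se.
#' @export
runPower <- function(config = simConfig(),
                     thetaGrid = c(0, 0.1, 0.2, 0.3, 0.4),
                     tauGrid = c(0, 0.02, 0.04), reps = 500L, alpha = 0.05,
                     seed = 1L,
                     rhoGrid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1)) {
  if (reps < 100L) stop("fewer than 100 replicates is not a power estimate")
  cells <- expand.grid(theta = thetaGrid, tau = tauGrid)
  cells <- cells[cells$theta != 0 | cells$tau != 0, , drop = FALSE]
  testCols <- c("pBurden", "pKm", "pFisher", "pAdapt", "pOptim", "pAcat")
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    cfg <- config
    cfg$theta <- cells$theta[ci]
    cfg$tau <- cells$tau[ci]
    rej <- matrix(NA, reps, length(testCols),
                  dimnames = list(NULL, testCols))
    for (i in seq_len(reps)) {
      set.seed(.childSeed(seed, i))
      r <- .runReplicate(cfg, "all", rhoGrid)
      rej[i, ] <- vapply(testCols, function(cn) r[[cn]] <= alpha, NA)
    }
    pw <- colMeans(rej, na.rm = TRUE)
    out[[ci]] <- data.frame(theta = cells$theta[ci], tau = cells$tau[ci],
                            test = sub("^p", "", testCols), power = pw,
                            se = sqrt(pw * (1 - pw) / reps),
                            row.names = NULL)
  }
  do.call(rbind, out)
}
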