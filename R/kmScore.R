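#' Tail probability of a mixture of 1-df chi-squares
#'
#' Computes \eqn{P(\sum_l \lambda_l \chi^2_1 > q)} by exact inversion of the
#' characteristic function (Imhof's integral, a Davies-type method).  If the
#' integrator fails or returns a value outside (0, 1], a Liu-Tang-Zhang
#' moment-matching approximation is used; if that also fails, a 1e6-draw
#' Monte-Carlo estimate.  The method actually used is recorded.  A rank-1
#' mixture is evaluated exactly as a scaled 1-df chi-square tail.
#'
#' @param q observed nonnegative quadratic-form value.
#' @param lambda positive mixture weights (the nonzero null eigenvalues).
#' @param acc absolute accuracy requested from the integrator (default 1e-12).
#' @return list with `p` (clamped to \[1e-300, 1\]) and `tailMethod`.
#' @examples
#' daviesPvalue(3.841459, 1)$p      # ~0.05
#' daviesPvalue(5.991465, c(1, 1))$p  # ~0.05
#' @export
daviesPvalue <- function(q, lambda, acc = 1e-12) {
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) stop("degenerate: no positive eigenvalues")
  if (!is.finite(q) || q < 0) stop("q must be nonnegative")
  if (q == 0) return(list(p = 1, tailMethod = "davies"))
  if (length(lambda) == 1L)
    return(list(p = max(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                        1e-300),
                tailMethod = "davies"))
  p <- .imhofTail(q, lambda, abs.tol = acc)
  if (!is.na(p) && p > 0 && p <= 1)
    return(list(p = max(p, 1e-300), tailMethod = "davies"))
  p <- .liuTail(q, lambda)
  if (!is.na(p) && p > 0 && p <= 1)
    return(list(p = max(p, 1e-300), tailMethod = "liu_moment"))
  list(p = max(.mcTail(q, lambda), 1e-300), tailMethod = "monte_carlo")
}

# Imhof (1961) inversion integral; vectorized integrand, NA on failure.
.imhofTail <- function(q, lambda, rel.tol = 1e-8, abs.tol = 1e-12) {
  f <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    sin(theta) * exp(-0.25 * colSums(log1p(lu^2))) / u
  }
  v <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = rel.tol, abs.tol = abs.tol,
                     subdivisions = 2000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(v) || !is.finite(v$value)) return(NA_real_)
  0.5 + v$value / pi
}

# Liu, Tang & Zhang (2009) moment-matched noncentral chi-square tail.
.liuTail <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2)); d <- s1 * a^3 - a^2; l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sqrt(2) * a + l + d, df = l, ncp = d,
                lower.tail = FALSE)
}

.mcTail <- function(q, lambda, nDraw = 1e6L) {
  S <- length(lambda)
  chunk <- max(1L, floor(2e6 / S))
  exceed <- 0
  done <- 0L
  while (done < nDraw) {
    m <- min(chunk, nDraw - done)
    draws <- colSums(lambda * matrix(stats::rchisq(S * m, df = 1), nrow = S))
    exceed <- exceed + sum(draws > q)
    done <- done + m
  }
  (exceed + 1) / (nDraw + 1)
}

# Upper quantile of the mixture at tail probability `level`: Liu-initialized
# bracket refined by uniroot on the Imhof tail.
.mixtureQuantile <- function(level, lambda, rel.tol = 1e-6) {
  if (length(lambda) == 1L)
    return(lambda * stats::qchisq(level, df = 1, lower.tail = FALSE))
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2)); d <- s1 * a^3 - a^2; l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  q0 <- c1 + sqrt(2 * c2) * (stats::qchisq(level, df = l, ncp = d,
                                           lower.tail = FALSE) - (l + d)) /
    (sqrt(2) * a)
  q0 <- max(q0, 1e-10)
  tail_at <- function(q) {
    p <- .imhofTail(q, lambda, rel.tol = rel.tol)
    if (is.na(p)) p <- .liuTail(q, lambda)
    p
  }
  lo <- q0 * 0.8; hi <- q0 * 1.25
  it <- 0L
  while (tail_at(lo) < level && it < 60L) { hi <- lo; lo <- lo * 0.6; it <- it + 1L }
  while (tail_at(hi) > level && it < 120L) { lo <- hi; hi <- hi * 1.6; it <- it + 1L }
  stats::uniroot(function(q) tail_at(q) - level, lower = lo, upper = hi,
                 tol = max(1e-6 * q0, 1e-10))$root
}

#' Kernel-machine variance-component score test in the Cox model
#'
#' Score test of the variance \eqn{\tau} of random per-SNP effects
#' \eqn{b_j \sim N(0, \tau)} under a linear kernel \eqn{K = G G^T}.  The
#' statistic is the quadratic form \eqn{Q = r^T G G^T r} in the null-model
#' martingale residuals.  Its null distribution is the chi-square mixture
#' \eqn{\sum_l \lambda_l \chi^2_1} with \eqn{\lambda_l} the nonzero
#' eigenvalues of \eqn{\tilde V^{1/2} K \tilde V^{1/2}}, where \eqn{V} is the
#' observed-information operator of the log partial likelihood in the linear
#' predictor at the null fit and \eqn{\tilde V} projects out the fitted null
#' design.  Eigenvalues are computed on the equivalent S x S cross-product
#' \eqn{G^T \tilde V G} and truncated below `1e-10 * max`.
#'
#' Fitting the null model on covariates only gives the plain variance-
#' component (KM) test; including the fitted eQTL-weighted burden score in
#' the null design gives the decorrelated variant whose statistic is
#' asymptotically independent of the burden Wald statistic.
#'
#' @param nullFit a [CoxFit-class] fitted on the same subjects (covariates
#'   only, or covariates plus the burden column for the decorrelated
#'   variant).
#' @param G genotype dosage matrix (subjects x SNPs) or
#'   [GenotypeMatrix-class], subject order matching `nullFit`.
#' @param acc tail accuracy passed to [daviesPvalue()].
#' @return a [KernelScoreResult-class].
#' @examples
#' sd <- SurvivalData(time = rexp(50) + 0.1, status = rbinom(50, 1, 0.7))
#' G <- matrix(rbinom(50 * 4, 2, 0.3), 50, 4)
#' kmScoreTest(fitCox(sd), G)
#' @export
kmScoreTest <- function(nullFit, G, acc = 1e-12) {
  stopifnot(is(nullFit, "CoxFit"))
  if (is(G, "GenotypeMatrix")) G <- dosages(G)
  G <- as.matrix(G)
  n <- length(nullFit@time)
  if (nrow(G) != n)
    stop("alignment error: genotype rows do not match the fitted subjects")
  if (anyNA(G)) stop("genotype matrix contains missing dosages; impute first")
  r <- nullFit@martingaleResiduals
  Gr <- crossprod(G, r)
  Q <- sum(Gr^2)
  if (all(G == 0))
    return(new("KernelScoreResult", Q = 0, eigenvalues = numeric(0),
               pValue = 1, tailMethod = "degenerate"))
  fac <- .coxInfoFactors(nullFit)
  M <- .coxInfoProduct(fac, G, G)
  X <- nullFit@design
  if (ncol(X) > 0) {
    GVX <- .coxInfoProduct(fac, G, X)
    XVX <- .coxInfoProduct(fac, X, X)
    M <- M - GVX %*% solve(XVX, t(GVX))
  }
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > 1e-10 * max(ev, 0)]
  if (!length(ev))
    return(new("KernelScoreResult", Q = Q, eigenvalues = numeric(0),
               pValue = 1, tailMethod = "degenerate"))
  tail <- daviesPvalue(Q, ev, acc = acc)
  new("KernelScoreResult", Q = Q, eigenvalues = sort(ev, decreasing = TRUE),
      pValue = tail$p, tailMethod = tail$tailMethod)
}
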