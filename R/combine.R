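.clampP <- function(p) {
  if (any(p <= 0)) {
    warning("p-value of 0 clamped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  pmin(p, 1)
}

#' Fisher's combination of two independent p-values
#'
#' \eqn{T = -2(\log p_\theta + \log p_\tau)} referred to a 4-df chi-square;
#' equivalently the closed form \eqn{e^{-T/2}(1 + T/2)}.  Valid because the
#' decorrelated two-stage construction makes the burden and variance-
#' component statistics asymptotically independent.
#'
#' @param pTheta,pTau component p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisherCombine(0.05, 0.05)  # ~0.0175
#' @export
fisherCombine <- function(pTheta, pTau) {
  p <- .clampP(c(pTheta, pTau))
  T <- -2 * sum(log(p))
  max(stats::pchisq(T, df = 4, lower.tail = FALSE), 1e-300)
}

#' Adaptively weighted combination of two independent p-values
#'
#' Binary-weight adaptive Fisher statistic: the three candidate statistics
#' are \eqn{Z_\theta} (vs chi-square 2), \eqn{Z_\tau} (vs chi-square 2) and
#' \eqn{Z_\theta + Z_\tau} (vs chi-square 4), with \eqn{Z = -2\log p}.  The
#' observed statistic is the minimum of the three candidate p-values (which
#' equal \eqn{p_\theta}, \eqn{p_\tau} and the Fisher p); the returned value
#' is the exact null probability, for independent uniforms, that this
#' minimum falls at or below the observed one, evaluated in closed form from
#' the piecewise integral of the joint region.
#'
#' @param pTheta,pTau component p-values in (0, 1].
#' @return combined p-value.  Symmetric in its arguments.
#' @examples
#' adaptCombine(0.05, 0.5)
#' @export
adaptCombine <- function(pTheta, pTau) {
  pp <- .clampP(c(pTheta, pTau))
  m <- min(pp, fisherCombine(pp[1], pp[2]))
  if (m >= 1) return(1)
  # t solves t(1 - log t) = m: the p1*p2 level set of the Fisher candidate
  t <- stats::uniroot(function(t) t * (1 - log(t)) - m,
                      lower = m * 1e-14, upper = m, tol = 1e-15)$root
  keep <- if (t <= m^2) {
    (1 - m)^2
  } else {
    a <- t / m   # always <= 1 since t <= m
    (a - m) - t * log(a / m) + (1 - m) * (1 - a)
  }
  min(max(1 - keep, m), 1)
}

#' Optimally weighted combination of the burden and variance-component tests
#'
#' Grid search over \eqn{T_\rho = \rho U_\theta + (1-\rho) U_\tau} with
#' \eqn{\rho \in} `rhoGrid`.  Under the null and independence of the two
#' components, \eqn{T_\rho} is the chi-square mixture with weights
#' \eqn{\{\rho\} \cup \{(1-\rho)\lambda_l\}}; each grid point gets its tail
#' probability, the observed statistic is the minimum \eqn{p_\rho}, and the
#' returned p-value is the exact null probability of that minimum, computed
#' by one-dimensional Gauss-Legendre integration over the 1-df chi-square
#' density of \eqn{U_\theta} (substituting \eqn{u = s^2} to remove the
#' density singularity at zero).  Ties on the argmin go to the smallest
#' \eqn{\rho}.
#'
#' @param uTheta burden Wald statistic (1-df chi-square scale).
#' @param km a [KernelScoreResult-class] from the decorrelated
#'   variance-component test (carries \eqn{U_\tau} and the null
#'   eigenvalues).
#' @param rhoGrid grid in \[0, 1\]; the default is denser near 0.  A
#'   single-point grid degenerates to that component's test.
#' @param nNodes Gauss-Legendre nodes for the calibration integral.
#' @return list with `p`, `rhoSelected`, `pRho`, `tRho`, `minP`.
#' @export
optimCombine <- function(uTheta, km,
                         rhoGrid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1),
                         nNodes = 40L) {
  stopifnot(is(km, "KernelScoreResult"))
  if (!length(rhoGrid)) stop("empty rho grid")
  rhoGrid <- sort(unique(rhoGrid))
  if (any(rhoGrid < 0 | rhoGrid > 1)) stop("rho grid must lie in [0, 1]")
  uTau <- km@Q
  lambda <- km@eigenvalues
  if (!length(lambda)) stop("variance-component result carries no eigenvalues")
  eigs <- lapply(rhoGrid, function(r) {
    e <- c(r, (1 - r) * lambda)
    e[e > 1e-12 * max(e)]
  })
  tRho <- rhoGrid * uTheta + (1 - rhoGrid) * uTau
  pRho <- vapply(seq_along(rhoGrid),
                 function(k) daviesPvalue(tRho[k], eigs[[k]])$p, 0)
  minP <- min(pRho)
  rhoSelected <- rhoGrid[which.min(pRho)]  # which.min takes first = smallest rho
  if (length(rhoGrid) == 1L)
    return(list(p = minP, rhoSelected = rhoSelected, pRho = pRho,
                tRho = tRho, minP = minP))
  qRho <- vapply(eigs, function(e) .mixtureQuantile(minP, e), 0)
  pos <- rhoGrid > 0
  uMax <- min(qRho[pos] / rhoGrid[pos])
  sMax <- sqrt(uMax)
  gl <- pracma::gaussLegendre(nNodes, 0, sMax)
  below1 <- rhoGrid < 1
  Fb <- vapply(gl$x, function(s) {
    b <- min((qRho[below1] - rhoGrid[below1] * s^2) / (1 - rhoGrid[below1]))
    if (b <= 0) return(0)
    tail <- .imhofTail(b, lambda, rel.tol = 1e-7)
    if (is.na(tail)) tail <- .liuTail(b, lambda)
    1 - min(max(tail, 0), 1)
  }, 0)
  keep <- sum(gl$w * Fb * 2 * stats::dnorm(gl$x))
  p <- 1 - keep
  p <- min(max(p, minP), min(1, minP * length(rhoGrid)))
  list(p = p, rhoSelected = rhoSelected, pRho = pRho, tRho = tRho, minP = minP)
}

#' Aggregated Cauchy combination (ACAT) of arbitrary p-values
#'
#' \eqn{T = \sum_i w_i \tan((0.5 - p_i)\pi) / \sum_i w_i}, with
#' \eqn{p = 0.5 - \arctan(T)/\pi}.  Valid for dependent inputs, which is why
#' it serves as the omnibus over the five component tests.  For
#' \eqn{p_i < 10^{-16}} the tangent term is replaced by its asymptote
#' \eqn{w_i/(p_i \pi)}; values at or above \eqn{1 - 10^{-16}} are clamped.
#'
#' @param p vector of p-values in (0, 1).
#' @param weights nonnegative weights (default equal).
#' @return combined p-value.
#' @examples
#' acatCombine(c(0.01, 0.5))  # ~0.0200
#' @export
acatCombine <- function(p, weights = NULL) {
  if (!length(p)) stop("empty p-value vector")
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p)) stop("weights length mismatch")
  if (any(weights < 0) || all(weights == 0)) stop("invalid weights")
  p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
  small <- p < 1e-16
  terms <- numeric(length(p))
  terms[!small] <- weights[!small] * tan((0.5 - p[!small]) * pi)
  terms[small] <- weights[small] / (p[small] * pi)
  T <- sum(terms) / sum(weights)
  max(min(0.5 - atan(T) / pi, 1), 1e-300)
}

#' Run the three joint combinations of the two decorrelated components
#'
#' Convenience wrapper producing a [CombinationResult-class] from the burden
#' Wald statistic/p-value and the decorrelated variance-component result.
#'
#' @param uTheta burden Wald statistic.
#' @param pTheta burden p-value.
#' @param km decorrelated [KernelScoreResult-class].
#' @param rhoGrid grid for [optimCombine()].
#' @return a [CombinationResult-class].
#' @export
jointTests <- function(uTheta, pTheta, km,
                       rhoGrid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1)) {
  pTau <- pValue(km)
  opt <- optimCombine(uTheta, km, rhoGrid = rhoGrid)
  new("CombinationResult",
      pFisher = fisherCombine(pTheta, pTau),
      pAdapt = adaptCombine(pTheta, pTau),
      pOptim = opt$p,
      rhoSelected = opt$rhoSelected,
      rhoGrid = sort(unique(rhoGrid)),
      zTheta = -2 * log(max(pTheta, 1e-300)),
      zTau = -2 * log(max(pTau, 1e-300)),
      tRho = opt$tRho)
}
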