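#' Fit a Cox proportional-hazards model by maximum partial likelihood
#'
#' Thin, fully-specified wrapper around [survival::coxph()] that returns the
#' quantities every SNP-set test downstream is built on: coefficients and
#' covariance, the maximized log partial likelihood, the linear predictor,
#' the Breslow baseline cumulative hazard, and martingale residuals.  An
#' empty design fits the null model (baseline hazard only).
#'
#' @param data a [SurvivalData-class] object.
#' @param design numeric matrix (subjects x q) of regressors, or NULL/0-column
#'   for the null model.  Constant or exactly collinear columns are refused:
#'   they carry no partial-likelihood information.
#' @param ties tie handling, `"efron"` (default) or `"breslow"`.
#' @param eps convergence tolerance on the relative change in the log partial
#'   likelihood (default 1e-9).
#' @param maxIter maximum Newton iterations (default 50; step-halving on
#'   likelihood decrease is handled by the underlying fitter).
#' @return a [CoxFit-class] object.  Non-convergence is flagged in
#'   `@converged`, not raised, so callers decide.
#' @examples
#' sd <- SurvivalData(time = c(1, 2, 3), status = c(1, 1, 1))
#' fit <- fitCox(sd, design = cbind(x = c(0, 1, 0)))
#' coef(fit)          # 0.5 * log(2)
#' @export
fitCox <- function(data, design = NULL, ties = c("efron", "breslow"),
                   eps = 1e-9, maxIter = 50L) {
  stopifnot(is(data, "SurvivalData"))
  ties <- match.arg(ties)
  n <- length(survTime(data))
  if (is.null(design)) design <- matrix(numeric(0), nrow = n, ncol = 0)
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  if (nrow(design) != n) stop("design rows do not match the number of subjects")
  q <- ncol(design)
  if (q > 0) {
    if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(q))
    sds <- apply(design, 2, stats::sd)
    if (any(sds == 0))
      stop("degenerate design: constant column(s) ",
           paste(colnames(design)[sds == 0], collapse = ", "))
    if (qr(design)$rank < q)
      stop("degenerate design: exactly collinear columns")
  }
  if (sum(eventStatus(data)) < 1) stop("no events: no partial-likelihood information")

  tt <- survTime(data)
  dd <- eventStatus(data)
  converged <- TRUE
  if (q == 0) {
    fit <- survival::coxph(survival::Surv(tt, dd) ~ 1, ties = ties)
    cf <- numeric(0)
    vc <- matrix(numeric(0), 0, 0)
    eta <- rep(0, n)
    ll <- fit$loglik[1L]
    nIter <- 0L
    resid <- unname(stats::residuals(fit, type = "martingale"))
  } else {
    df <- data.frame(design, check.names = FALSE)
    fml <- stats::as.formula(paste(
      "survival::Surv(tt, dd) ~",
      paste(sprintf("`%s`", colnames(design)), collapse = " + ")))
    fit <- withCallingHandlers(
      survival::coxph(fml, data = df, ties = ties,
                      control = survival::coxph.control(eps = eps,
                                                        iter.max = maxIter)),
      warning = function(w) {
        if (grepl("Ran out of iterations|did not converge", conditionMessage(w))) {
          converged <<- FALSE
          invokeRestart("muffleWarning")
        }
      })
    cf <- stats::setNames(unname(stats::coef(fit)), colnames(design))
    if (anyNA(cf)) stop("degenerate design: coefficients not estimable")
    vc <- unname(stats::vcov(fit))
    dimnames(vc) <- list(colnames(design), colnames(design))
    eta <- as.vector(design %*% cf)
    ll <- fit$loglik[2L]
    nIter <- as.integer(fit$iter[1L])
    resid <- unname(stats::residuals(fit, type = "martingale"))
  }

  new("CoxFit", coefficients = cf, vcov = vc, logLik = ll,
      linearPredictor = eta, baselineCumhaz = breslowCumhaz(tt, dd, eta),
      martingaleResiduals = resid, converged = converged,
      nIter = nIter, design = design, time = tt, status = dd, ties = ties)
}

#' Breslow estimator of the baseline cumulative hazard
#'
#' \eqn{\hat\Lambda_0(t) = \sum_{t_k \le t} d_k / \sum_{j: t_j \ge t_k}
#' e^{\eta_j}}, a right-continuous step function evaluated at the distinct
#' event times.
#'
#' @param time,status observed times and 0/1 event indicators.
#' @param eta linear predictor at which to evaluate (default all zero).
#' @return data.frame with columns `time` and `cumhaz`.
#' @export
breslowCumhaz <- function(time, status, eta = rep(0, length(time))) {
  w <- exp(eta)
  evt <- sort(unique(time[status == 1]))
  inc <- vapply(evt, function(tk) {
    sum(status == 1 & time == tk) / sum(w[time >= tk])
  }, 0)
  data.frame(time = evt, cumhaz = cumsum(inc))
}

#' Wald test of one Cox coefficient
#'
#' Chi-square(1) Wald statistic \eqn{(\hat\beta/\mathrm{se})^2} for one
#' coefficient of a converged fit; this is the burden test when applied to
#' the eQTL-weighted score column.
#'
#' @param fit a converged [CoxFit-class].
#' @param index coefficient position or name (default 1).
#' @return list with `statistic` and `p.value`.
#' @examples
#' sd <- SurvivalData(time = c(1, 2, 3), status = c(1, 1, 1))
#' waldTest(fitCox(sd, cbind(x = c(0, 1, 0))))
#' @export
waldTest <- function(fit, index = 1L) {
  stopifnot(is(fit, "CoxFit"))
  if (!fit@converged) stop("fit did not converge; Wald test unavailable")
  if (is.character(index)) index <- match(index, names(fit@coefficients))
  if (is.na(index) || index < 1L || index > length(fit@coefficients))
    stop("no such coefficient")
  v <- fit@vcov[index, index]
  if (!is.finite(v) || v <= 0) stop("degenerate variance estimate")
  stat <- unname(fit@coefficients[index]^2 / v)
  list(statistic = stat,
       p.value = max(stats::pchisq(stat, df = 1, lower.tail = FALSE), 1e-300))
}

# Per-event risk-set weight columns of the observed-information operator of
# the log partial likelihood in the linear predictor.  V = diag(h) - W W^T
# with h = rowSums(W); each column of W is e^eta restricted to one (sub-)event
# risk set and normalized by its denominator.  Under Efron ties each tied
# group of size d contributes d columns with the tied subjects progressively
# down-weighted by (l-1)/d; with no ties this reduces to the Breslow form.
# V annihilates constants (V 1 = 0), so dosage centering is immaterial.
.coxInfoFactors <- function(fit) {
  eta <- fit@linearPredictor
  time <- fit@time
  status <- fit@status
  w <- exp(eta)
  evt <- sort(unique(time[status == 1]))
  cols <- vector("list", length(evt))
  for (k in seq_along(evt)) {
    tk <- evt[k]
    risk <- as.numeric(time >= tk)
    inD <- as.numeric(time == tk & status == 1)
    dk <- sum(inD)
    if (fit@ties == "breslow" || dk == 1L) {
      # d_k copies of the shared risk-set column carry the d_k multiplicity
      cols[[k]] <- matrix(rep(w * risk / sum(w * risk), dk), ncol = dk)
    } else {
      frac <- (seq_len(dk) - 1L) / dk
      Sfull <- sum(w * risk)
      Sd <- sum(w * inD)
      Wk <- vapply(frac, function(f) w * (risk - f * inD) / (Sfull - f * Sd),
                   numeric(length(w)))
      cols[[k]] <- Wk
    }
  }
  W <- do.call(cbind, cols)
  list(W = W, h = rowSums(W))
}

# A^T V B without forming the n x n operator.
.coxInfoProduct <- function(factors, A, B) {
  crossprod(A, factors$h * B) - crossprod(A, factors$W) %*% crossprod(factors$W, B)
}
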