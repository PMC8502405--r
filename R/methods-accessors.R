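#' @rdname accessors
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @rdname accessors
setMethod("snpIds", "GenotypeMatrix", function(x) colnames(x@dosage))

#' @rdname accessors
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname accessors
setMethod("effectAlleles", "GenotypeMatrix", function(x)
  stats::setNames(x@effectAllele, snpIds(x)))

#' @rdname accessors
setMethod("otherAlleles", "GenotypeMatrix", function(x)
  stats::setNames(x@otherAllele, snpIds(x)))

#' @rdname accessors
setMethod("mafs", "GenotypeMatrix", function(x) {
  af <- colMeans(x@dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  pmin(af, 1 - af)
})

#' @rdname accessors
setMethod("missingness", "GenotypeMatrix", function(x)
  colMeans(is.na(x@dosage)))

#' @rdname accessors
setMethod("sampleIds", "SurvivalData", function(x) x@subjectId)

#' @rdname accessors
setMethod("survTime", "SurvivalData", function(x) x@time)

#' @rdname accessors
setMethod("eventStatus", "SurvivalData", function(x) x@status)

#' @rdname accessors
setMethod("covariates", "SurvivalData", function(x) x@covariates)

#' @rdname accessors
setMethod("snpIds", "EqtlWeights", function(x) x@snp)

#' @rdname accessors
setMethod("effectAlleles", "EqtlWeights", function(x)
  stats::setNames(x@effectAllele, x@snp))

#' @rdname accessors
setMethod("otherAlleles", "EqtlWeights", function(x)
  stats::setNames(x@otherAllele, x@snp))

#' @rdname accessors
setMethod("weightBetas", "EqtlWeights", function(x)
  stats::setNames(x@beta, x@snp))

#' @rdname accessors
setMethod("martingaleResiduals", "CoxFit", function(x) x@martingaleResiduals)

#' @rdname accessors
setMethod("baselineCumhaz", "CoxFit", function(x) x@baselineCumhaz)

#' @rdname accessors
#' @param object a CoxFit.
#' @export
setMethod("coef", "CoxFit", function(object) object@coefficients)

#' @rdname accessors
#' @export
setMethod("vcov", "CoxFit", function(object) object@vcov)

#' @rdname accessors
#' @export
setMethod("logLik", "CoxFit", function(object) object@logLik)

#' @rdname accessors
setMethod("scoreStatistic", "KernelScoreResult", function(x) x@Q)

#' @rdname accessors
setMethod("nullEigenvalues", "KernelScoreResult", function(x) x@eigenvalues)

#' @rdname accessors
setMethod("pValue", "KernelScoreResult", function(x) x@pValue)

#' @rdname accessors
setMethod("tailMethod", "KernelScoreResult", function(x) x@tailMethod)

#' @rdname subsetGenotypes
#' @param x a GenotypeMatrix.
#' @param samples,snps ids or indices; NULL keeps all.
setMethod("subsetGenotypes", "GenotypeMatrix", function(x, samples = NULL,
                                                        snps = NULL) {
  d <- x@dosage
  ridx <- if (is.null(samples)) seq_len(nrow(d)) else {
    if (is.character(samples)) match(samples, rownames(d)) else samples
  }
  cidx <- if (is.null(snps)) seq_len(ncol(d)) else {
    if (is.character(snps)) match(snps, colnames(d)) else snps
  }
  if (anyNA(ridx)) stop("unknown sample ids in subset")
  if (anyNA(cidx)) stop("unknown SNP ids in subset")
  new("GenotypeMatrix", dosage = d[ridx, cidx, drop = FALSE],
      effectAllele = x@effectAllele[cidx], otherAllele = x@otherAllele[cidx],
      chrom = x@chrom[cidx], pos = x@pos[cidx])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "SNPs\n")
  m <- mafs(object)
  if (length(m)) {
    cat("  MAF range:", paste(signif(range(m, na.rm = TRUE), 3), collapse = " - "),
        "\n  missingness:", signif(mean(missingness(object)), 3), "\n")
  }
})

setMethod("show", "SurvivalData", function(object) {
  cat("SurvivalData:", length(object@time), "subjects,",
      sum(object@status), "events (",
      signif(100 * mean(object@status == 0), 3), "% censored ),",
      ncol(object@covariates), "covariates\n")
})

setMethod("show", "EqtlWeights", function(object) {
  cat("EqtlWeights for gene", object@gene, ":", length(object@snp),
      "SNPs, |beta| range",
      paste(signif(range(abs(object@beta)), 3), collapse = " - "), "\n")
})

setMethod("show", "CoxFit", function(object) {
  cat("CoxFit:", length(object@time), "subjects,", sum(object@status),
      "events,", length(object@coefficients), "coefficients (",
      object@ties, "ties ),",
      if (object@converged) "converged" else "NOT converged",
      "in", object@nIter, "iterations\n")
  if (length(object@coefficients)) {
    se <- sqrt(diag(object@vcov))
    print(data.frame(coef = object@coefficients, se = se,
                     row.names = names(object@coefficients)))
  }
})

setMethod("show", "KernelScoreResult", function(object) {
  cat("KernelScoreResult: Q =", signif(object@Q, 5), ", rank",
      length(object@eigenvalues), ", p =", format(object@pValue, digits = 4),
      "(", object@tailMethod, ")\n")
})

setMethod("show", "CombinationResult", function(object) {
  cat("CombinationResult: Fisher p =", format(object@pFisher, digits = 4),
      ", adapt p =", format(object@pAdapt, digits = 4),
      ", optim p =", format(object@pOptim, digits = 4),
      "(rho =", object@rhoSelected, ")\n")
})
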