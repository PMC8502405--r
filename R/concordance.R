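#' Marginal per-SNP Cox effect sizes
#'
#' One Cox fit per SNP with design \eqn{[g_j, X]} (covariate-adjusted),
#' returning the genotype log-hazard coefficient.  Monomorphic or
#' non-converging SNPs yield NA with a message rather than aborting.
#'
#' @param G dosage matrix or [GenotypeMatrix-class] (QC'd, no missing
#'   entries).
#' @param pheno a [SurvivalData-class] on the same subjects, same order.
#' @param ties tie handling passed to [fitCox()].
#' @return named numeric vector of per-SNP effects (NA where estimation
#'   failed).
#' @export
marginalCoxEffects <- function(G, pheno, ties = "efron") {
  if (is(G, "GenotypeMatrix")) G <- dosages(G)
  G <- as.matrix(G)
  X <- covariates(pheno)
  vapply(stats::setNames(seq_len(ncol(G)), colnames(G)), function(j) {
    tryCatch({
      fit <- fitCox(pheno, cbind(g = G[, j], X), ties = ties)
      if (!fit@converged) stop("not converged")
      unname(coef(fit)[1L])
    }, error = function(e) {
      message("SNP ", colnames(G)[j], " skipped: ", conditionMessage(e))
      NA_real_
    })
  }, 0)
}

#' Per-gene regression of survival effects on eQTL effects
#'
#' Ordinary least squares with intercept of the per-SNP marginal survival
#' log-hazard estimates (response) on the per-SNP eQTL effect sizes
#' (covariate) for one gene; returns the slope, its t-test p-value and R
#' squared.  Requires at least 3 shared SNPs (degrees of freedom for the
#' slope test); a zero-variance covariate yields an undefined-slope flag.
#'
#' @param survEffects per-SNP survival effects (response).
#' @param eqtlEffects per-SNP eQTL effects (covariate), same length/order.
#' @param gene gene identifier carried through to the output.
#' @return one-row data.frame: gene, n_snps, slope, se, p, r2, flag.
#' @export
geneRegression <- function(survEffects, eqtlEffects, gene = NA_character_) {
  ok <- is.finite(survEffects) & is.finite(eqtlEffects)
  y <- survEffects[ok]; x <- eqtlEffects[ok]
  bad <- function(flag) data.frame(gene = gene, n_snps = length(y),
                                   slope = NA_real_, se = NA_real_,
                                   p = NA_real_, r2 = NA_real_, flag = flag,
                                   stringsAsFactors = FALSE)
  if (length(y) < 3L) return(bad("too_few_snps"))
  if (stats::var(x) == 0) return(bad("zero_variance_covariate"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(gene = gene, n_snps = length(y),
             slope = unname(stats::coef(fit)[2L]),
             se = sm$coefficients[2L, 2L],
             p = sm$coefficients[2L, 4L],
             r2 = sm$r.squared, flag = "ok", stringsAsFactors = FALSE)
}

#' Study-wide effect-size concordance table
#'
#' Applies [geneRegression()] per gene and Benjamini-Hochberg adjustment of
#' the slope p-values across genes.
#'
#' @param pairs data.frame with columns gene, surv_effect, eqtl_effect (one
#'   row per SNP).
#' @return data.frame of per-gene regressions with a q column.
#' @export
concordanceTable <- function(pairs) {
  stopifnot(all(c("gene", "surv_effect", "eqtl_effect") %in% names(pairs)))
  rows <- lapply(split(pairs, pairs$gene), function(df)
    geneRegression(df$surv_effect, df$eqtl_effect, gene = df$gene[1L]))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bhFdr(out$p)
  out
}

#' Detection-rate enrichment chi-square test on a 2x2 table
#'
#' Tests whether the rate of nominally significant joint-test genes differs
#' between genes with and without a significant effect-size regression.
#' Pearson 1-df chi-square with the Yates continuity correction
#' (min(0.5, |O - E|) subtracted from each |O - E|), plus the detection-rate
#' ratio (a/(a+b)) / (c/(c+d)).
#'
#' @param a,b joint-test significant / non-significant counts among genes
#'   with regression FDR < threshold.
#' @param c,d the same among genes with regression FDR >= threshold.
#' @return list with `statistic`, `p.value`, `rateRatio`, `rates`.
#' @examples
#' enrichmentTest(259, 8274, 19, 2611)  # p ~ 4.6e-11
#' @export
enrichmentTest <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("untestable: zero margin")
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  r1 <- a / (a + b); r2 <- c / (c + d)
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       rateRatio = r1 / r2, rates = c(r1, r2))
}
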