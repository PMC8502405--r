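#' Analysis configuration
#'
#' QC thresholds mirror common GWAS practice for typical cohort genotype
#' data: MAF >= 0.01, per-SNP missingness <= 0.05, Hardy-Weinberg exact-fit
#' chi-square p >= 1e-4.  The FDR reporting level defaults to 0.1.
#'
#' @param mafMin minimum folded minor-allele frequency.
#' @param missMax maximum per-SNP missingness.
#' @param hweAlpha Hardy-Weinberg chi-square rejection level.
#' @param rhoGrid grid for the optimal combination (denser near 0).
#' @param standardize standardize clinical covariates before fitting
#'   (on by default; switch off to use covariates as supplied).
#' @param fdrLevel FDR level used when flagging significant genes.
#' @param seed optional integer seed recorded for reproducibility.
#' @return a list of class `iehc_config`.
#' @export
iehcConfig <- function(mafMin = 0.01, missMax = 0.05, hweAlpha = 1e-4,
                       rhoGrid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1),
                       standardize = TRUE, fdrLevel = 0.1, seed = NULL) {
  stopifnot(mafMin >= 0, mafMin <= 0.5, missMax >= 0, missMax <= 1,
            hweAlpha >= 0, hweAlpha <= 1, all(rhoGrid >= 0 & rhoGrid <= 1))
  structure(list(mafMin = mafMin, missMax = missMax, hweAlpha = hweAlpha,
                 rhoGrid = sort(unique(rhoGrid)), standardize = standardize,
                 fdrLevel = fdrLevel, seed = seed),
            class = "iehc_config")
}

#' Hardy-Weinberg equilibrium chi-square test from genotype counts
#'
#' 1-df Pearson chi-square of the observed (hom-ref, het, hom-alt) counts
#' against the Hardy-Weinberg expectation at the estimated allele frequency.
#'
#' @param n0,n1,n2 genotype counts (0, 1 and 2 copies of the effect allele).
#' @return list with `statistic` and `p.value`.
#' @examples
#' hweTest(25, 50, 25)  # perfect proportions: statistic 0, p 1
#' hweTest(30, 40, 30)  # statistic 4, p ~0.0455
#' @export
hweTest <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(list(statistic = NA_real_, p.value = NA_real_))
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n0, n1, n2)
  if (any(e == 0)) return(list(statistic = 0, p.value = 1))
  stat <- sum((o - e)^2 / e)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-SNP quality control
#'
#' Removes SNPs with folded MAF below `mafMin`, missingness above `missMax`,
#' or Hardy-Weinberg chi-square p below `hweAlpha` (tested on integer-called
#' genotypes only; SNPs with fractional dosages skip the HWE filter).
#' Residual missing dosages of the surviving SNPs are mean-imputed per SNP.
#'
#' @param G a [GenotypeMatrix-class].
#' @param mafMin,missMax,hweAlpha thresholds (see [iehcConfig()]).
#' @return a [GenotypeMatrix-class] with failing SNPs dropped and no missing
#'   entries; may have zero SNPs left.
#' @export
snpQC <- function(G, mafMin = 0.01, missMax = 0.05, hweAlpha = 1e-4) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- dosages(G)
  maf <- mafs(G)
  miss <- missingness(G)
  hweP <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    g <- g[!is.na(g)]
    if (!length(g) || any(g != round(g))) return(1)
    hweTest(sum(g == 0), sum(g == 1), sum(g == 2))$p.value
  }, 0)
  keep <- !is.na(maf) & maf >= mafMin & miss <= missMax & hweP >= hweAlpha
  out <- subsetGenotypes(G, snps = which(keep))
  d <- dosages(out)
  if (anyNA(d)) {
    for (j in which(colSums(is.na(d)) > 0)) {
      mj <- mean(d[, j], na.rm = TRUE)
      d[is.na(d[, j]), j] <- mj
    }
    out@dosage <- d
  }
  out
}

.AMBIGUOUS <- c(A = "T", T = "A", C = "G", G = "C")

#' Align eQTL weights to genotype effect alleles
#'
#' Intersects the SNPs of a weight set with a genotype matrix and makes the
#' orientation consistent: strand-ambiguous SNPs (A/T, C/G) are dropped, as
#' are SNPs whose allele pairs do not match; SNPs whose effect and other
#' alleles are swapped between the two sources have their weight negated and
#' their dosage recoded as 2 - g (an involution; the product beta * g is
#' invariant up to a constant the Cox baseline absorbs).  On output the
#' weight effect alleles match the genotype effect alleles exactly.  If the
#' genotype matrix carries no allele metadata the intersection is by SNP id
#' only, with a warning.
#'
#' @param G a [GenotypeMatrix-class].
#' @param W an [EqtlWeights-class].
#' @return list with elements `G` and `W`, restricted to the aligned SNPs
#'   (possibly zero).
#' @export
alignAlleles <- function(G, W) {
  stopifnot(is(G, "GenotypeMatrix"), is(W, "EqtlWeights"))
  shared <- intersect(snpIds(G), snpIds(W))
  G <- subsetGenotypes(G, snps = shared)
  widx <- match(shared, snpIds(W))
  wEff <- W@effectAllele[widx]; wOth <- W@otherAllele[widx]
  beta <- W@beta[widx]
  gEff <- G@effectAllele; gOth <- G@otherAllele
  if (all(is.na(gEff))) {
    warning("genotype matrix carries no allele metadata; matching by id only")
    Wout <- EqtlWeights(W@gene, shared, wEff, wOth, beta)
    return(list(G = G, W = Wout))
  }
  ambiguous <- !is.na(gEff) & .AMBIGUOUS[gEff] == gOth
  same <- gEff == wEff & gOth == wOth
  swapped <- gEff == wOth & gOth == wEff
  keep <- which(!ambiguous & (same | swapped))
  G <- subsetGenotypes(G, snps = keep)
  flip <- swapped[keep]
  betaKeep <- beta[keep]
  if (any(flip)) {
    G@dosage[, flip] <- 2 - G@dosage[, flip]
    tmp <- G@effectAllele[flip]
    G@effectAllele[flip] <- G@otherAllele[flip]
    G@otherAllele[flip] <- tmp
    betaKeep[flip] <- -betaKeep[flip]
  }
  Wout <- EqtlWeights(W@gene, snpIds(G), G@effectAllele, G@otherAllele,
                      betaKeep)
  list(G = G, W = Wout)
}

#' Core SNP-set survival tests for one gene
#'
#' Runs the six tests on already-QC'd, already-aligned inputs:
#' \enumerate{
#'   \item burden: Wald test of the eQTL-weighted score \eqn{s = G\beta} in
#'     the Cox model with design \eqn{[s, X]};
#'   \item plain variance-component (KM) test with the null fitted on the
#'     covariates only;
#'   \item decorrelated variance-component test with the null fitted on
#'     \eqn{[s, X]} (the burden term fitted, not constrained to zero), which
#'     makes \eqn{U_\tau} asymptotically independent of \eqn{U_\theta};
#'   \item Fisher / adapt / optim combinations of the burden p (or
#'     \eqn{U_\theta}) with the decorrelated component;
#'   \item ACAT omnibus over the five p-values (burden, plain KM, Fisher,
#'     adapt, optim) with equal weights.
#' }
#' A degenerate burden score (constant, e.g. all weights zero) flags the
#' burden and joint tests at p = 1; the plain KM test still runs.
#'
#' @param G dosage matrix or [GenotypeMatrix-class] (no missing entries).
#' @param w numeric weight per SNP (aligned order).
#' @param pheno a [SurvivalData-class] on the same subjects, same order.
#' @param X covariate matrix (defaults to the phenotype covariates).
#' @param rhoGrid grid for [optimCombine()].
#' @param tests `"all"` for the six tests or `"components"` for only the
#'   burden statistic and the decorrelated variance component (used by the
#'   statistic-independence experiment).
#' @return list of statistics and p-values (`uTheta`, `pBurden`, `uTau`,
#'   `pTauDecor`, `pKm`, `pFisher`, `pAdapt`, `pOptim`, `pAcat`,
#'   `rhoSelected`, `degenerateBurden`).
#' @export
iehcTest <- function(G, w, pheno, X = covariates(pheno),
                     rhoGrid = c(0, 0.01, 0.04, 0.09, 0.25, 0.5, 1),
                     tests = c("all", "components")) {
  tests <- match.arg(tests)
  if (is(G, "GenotypeMatrix")) G <- dosages(G)
  G <- as.matrix(G)
  stopifnot(length(w) == ncol(G))
  s <- as.vector(G %*% w)
  degenerate <- stats::sd(s) < 1e-12

  out <- list(uTheta = NA_real_, pBurden = 1, uTau = NA_real_,
              pTauDecor = NA_real_, pKm = NA_real_, pFisher = 1,
              pAdapt = 1, pOptim = 1, pAcat = NA_real_,
              rhoSelected = NA_real_, degenerateBurden = degenerate)

  if (!degenerate) {
    fitB <- fitCox(pheno, cbind(burden = s, X))
    wt <- waldTest(fitB, 1L)
    out$uTheta <- wt$statistic
    out$pBurden <- wt$p.value
    kmDecor <- kmScoreTest(fitB, G)
    out$uTau <- scoreStatistic(kmDecor)
    out$pTauDecor <- pValue(kmDecor)
  }

  if (tests == "components") {
    return(out)
  }

  fit0 <- fitCox(pheno, X)
  kmPlain <- kmScoreTest(fit0, G)
  out$pKm <- pValue(kmPlain)

  if (!degenerate) {
    comb <- jointTests(out$uTheta, out$pBurden, kmDecor, rhoGrid = rhoGrid)
    out$pFisher <- comb@pFisher
    out$pAdapt <- comb@pAdapt
    out$pOptim <- comb@pOptim
    out$rhoSelected <- comb@rhoSelected
  }
  out$pAcat <- acatCombine(c(out$pBurden, out$pKm, out$pFisher,
                             out$pAdapt, out$pOptim))
  out
}

# Center all columns, scale the non-constant ones (a constant covariate has
# no scale and would otherwise become NaN).
.standardizeCovariates <- function(X) {
  ctr <- scale(X, scale = FALSE)
  sds <- apply(X, 2, stats::sd)
  nz <- sds > 0
  ctr[, nz] <- sweep(ctr[, nz, drop = FALSE], 2, sds[nz], "/")
  ctr
}

.naGeneRow <- function(gene, sUsed, reason) {
  data.frame(gene = gene, S = sUsed, U_theta = NA_real_,
             p_burden = NA_real_, p_km = NA_real_, p_fisher = NA_real_,
             p_adapt = NA_real_, p_optim = NA_real_, p_acat = NA_real_,
             degenerate_burden = NA, reason = reason,
             stringsAsFactors = FALSE)
}

#' Run all six tests for one gene
#'
#' Per-gene orchestration: sample intersection, SNP QC, allele alignment,
#' burden-score construction and the six tests.  Failures (no SNP surviving
#' QC, no shared SNPs, non-convergence) yield an NA row with the reason
#' recorded rather than an error, so a study never aborts for one bad gene.
#'
#' @param G a [GenotypeMatrix-class].
#' @param W an [EqtlWeights-class] for the gene.
#' @param pheno a [SurvivalData-class].
#' @param config an [iehcConfig()] list.
#' @return one-row data.frame with columns gene, S, U_theta, p_burden, p_km,
#'   p_fisher, p_adapt, p_optim, p_acat, degenerate_burden, reason.
#' @export
runGene <- function(G, W, pheno, config = iehcConfig()) {
  stopifnot(is(G, "GenotypeMatrix"), is(W, "EqtlWeights"),
            is(pheno, "SurvivalData"))
  common <- intersect(sampleIds(pheno), sampleIds(G))
  if (length(common) < 2)
    return(.naGeneRow(W@gene, 0L, "no_shared_samples"))
  keep <- match(common, sampleIds(pheno))
  ph <- SurvivalData(time = survTime(pheno)[keep],
                     status = eventStatus(pheno)[keep],
                     covariates = covariates(pheno)[keep, , drop = FALSE],
                     subjectId = common)
  G <- subsetGenotypes(G, samples = common)

  res <- tryCatch({
    Gq <- snpQC(G, config$mafMin, config$missMax, config$hweAlpha)
    if (ncol(dosages(Gq)) == 0)
      return(.naGeneRow(W@gene, 0L, "qc_removed_all_snps"))
    al <- alignAlleles(Gq, W)
    if (ncol(dosages(al$G)) == 0)
      return(.naGeneRow(W@gene, 0L, "no_aligned_snps"))
    X <- covariates(ph)
    if (config$standardize && ncol(X) > 0) {
      X <- .standardizeCovariates(X)
      ph@covariates <- X
    }
    tst <- iehcTest(al$G, weightBetas(al$W), ph, X = X,
                    rhoGrid = config$rhoGrid)
    data.frame(gene = W@gene, S = ncol(dosages(al$G)),
               U_theta = tst$uTheta, p_burden = tst$pBurden,
               p_km = tst$pKm, p_fisher = tst$pFisher,
               p_adapt = tst$pAdapt, p_optim = tst$pOptim,
               p_acat = tst$pAcat,
               degenerate_burden = tst$degenerateBurden,
               reason = if (tst$degenerateBurden) "degenerate_burden" else "ok",
               stringsAsFactors = FALSE)
  }, error = function(e) .naGeneRow(W@gene, NA_integer_,
                                    paste0("error: ", conditionMessage(e))))
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' computed over the non-missing entries (missing p-values stay missing and
#' do not count toward the number of tests).
#'
#' @param p vector of p-values in (0, 1], NA allowed.
#' @return q-values, same length and order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

# Resolve a gene definition (character snp-id vector, or a list with a
# `region` of chrom/start/end, 1-based inclusive) against a genotype matrix.
# Explicit snp ids take precedence over region overlap.
.resolveGeneSnps <- function(def, G) {
  if (is.character(def)) return(intersect(def, snpIds(G)))
  if (is.list(def) && !is.null(def$snps)) return(intersect(def$snps, snpIds(G)))
  if (is.list(def) && !is.null(def$region)) {
    rg <- def$region
    hit <- !is.na(G@chrom) & G@chrom == as.character(rg$chrom) &
      !is.na(G@pos) & G@pos >= as.numeric(rg$start) &
      G@pos <= as.numeric(rg$end)
    return(snpIds(G)[hit])
  }
  character(0)
}

#' Run a study across genes with per-test FDR
#'
#' Applies [runGene()] to every gene in input order, then Benjamini-Hochberg
#' adjustment per test column across genes.  Genes failing QC are reported
#' with NA p-values (reason recorded) rather than omitted.
#'
#' @param genes named list of gene definitions: each element a character
#'   vector of SNP ids, or a list with `snps` and/or
#'   `region = list(chrom, start, end)` (1-based inclusive; SNP ids take
#'   precedence over region overlap).
#' @param G a [GenotypeMatrix-class] holding all SNPs.
#' @param W a data.frame of weights with columns gene, snp, effect_allele,
#'   other_allele, beta (as from [readWeights()]), or a named list of
#'   [EqtlWeights-class] objects.
#' @param pheno a [SurvivalData-class].
#' @param config an [iehcConfig()] list.
#' @return data.frame with one row per gene and q_* columns per test.
#' @export
runStudy <- function(genes, G, W, pheno, config = iehcConfig()) {
  stopifnot(length(genes) >= 1, !is.null(names(genes)))
  rows <- lapply(names(genes), function(g) {
    snps <- .resolveGeneSnps(genes[[g]], G)
    wg <- .geneWeights(W, g)
    if (!length(snps)) return(.naGeneRow(g, 0L, "no_snps_in_genotypes"))
    if (is.null(wg)) return(.naGeneRow(g, 0L, "no_weights"))
    Gg <- subsetGenotypes(G, snps = snps)
    row <- runGene(Gg, wg, pheno, config)
    row$gene <- g
    row
  })
  out <- do.call(rbind, rows)
  for (col in c("p_burden", "p_km", "p_fisher", "p_adapt", "p_optim", "p_acat"))
    out[[sub("p_", "q_", col)]] <- bhFdr(out[[col]])
  out
}

.geneWeights <- function(W, gene) {
  if (is.list(W) && !is.data.frame(W)) {
    w <- W[[gene]]
    if (is.null(w)) return(NULL)
    stopifnot(is(w, "EqtlWeights"))
    return(w)
  }
  rows <- W[W$gene == gene, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  EqtlWeights(gene, rows$snp, rows$effect_allele, rows$other_allele, rows$beta)
}
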