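#' @import methods
NULL

#' Survival phenotype container
#'
#' Holds observed follow-up times, event indicators and the clinical
#' covariate matrix for one cohort.  Times must be positive, the status
#' indicator is 1 for an observed event and 0 for a right-censored record,
#' and at least one event must be present for any partial-likelihood fit to
#' carry information.
#'
#' @slot subjectId character vector of unique sample identifiers.
#' @slot time numeric vector of positive observed times.
#' @slot status numeric vector of 0/1 event indicators.
#' @slot covariates numeric matrix (subjects x covariates), no missing
#'   entries; may have zero columns.
#'
#' @exportClass SurvivalData
setClass("SurvivalData",
  representation(
    subjectId = "character",
    time = "numeric",
    status = "numeric",
    covariates = "matrix"
  )
)

setValidity("SurvivalData", function(object) {
  n <- length(object@time)
  msg <- character()
  if (n < 2L) msg <- c(msg, "need at least 2 subjects")
  if (length(object@subjectId) != n) msg <- c(msg, "subjectId length mismatch")
  if (anyDuplicated(object@subjectId)) msg <- c(msg, "duplicate subject ids")
  if (length(object@status) != n) msg <- c(msg, "status length mismatch")
  if (nrow(object@covariates) != n) msg <- c(msg, "covariate row mismatch")
  if (any(!is.finite(object@time)) || any(object@time <= 0))
    msg <- c(msg, "all times must be finite and > 0")
  if (!all(object@status %in% c(0, 1)))
    msg <- c(msg, "status must be 0/1")
  if (sum(object@status) < 1) msg <- c(msg, "at least one event required")
  if (anyNA(object@covariates)) msg <- c(msg, "covariates contain missing values")
  if (length(msg)) msg else TRUE
})

#' Construct a SurvivalData object
#'
#' @param time positive observed times.
#' @param status 0/1 event indicators (1 = event).
#' @param covariates optional numeric matrix or data.frame of clinical
#'   covariates; coerced to a numeric matrix.
#' @param subjectId optional sample identifiers (defaults to s1, s2, ...).
#' @return A [SurvivalData-class] object.
#' @examples
#' sd <- SurvivalData(time = c(2, 5, 3), status = c(1, 0, 1))
#' @export
SurvivalData <- function(time, status, covariates = NULL, subjectId = NULL) {
  n <- length(time)
  if (is.null(subjectId)) subjectId <- paste0("s", seq_len(n))
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
  }
  rownames(covariates) <- subjectId
  new("SurvivalData", subjectId = as.character(subjectId),
      time = as.numeric(time), status = as.numeric(status),
      covariates = covariates)
}

#' Genotype dosage container
#'
#' Dosage matrix (subjects x SNPs) coded as the count of the effect allele
#' (0, 1 or 2; NA for missing calls, fractional values after mean
#' imputation), with per-SNP allele labels and optional genomic coordinates.
#'
#' @slot dosage numeric matrix with sample ids as rownames and SNP ids as
#'   colnames; entries in \[0, 2\] or NA.
#' @slot effectAllele character vector (one per SNP); the counted allele.
#' @slot otherAllele character vector (one per SNP).
#' @slot chrom character vector of chromosome labels (NA if unknown).
#' @slot pos numeric vector of 1-based positions (NA if unknown).
#'
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(
    dosage = "matrix",
    effectAllele = "character",
    otherAllele = "character",
    chrom = "character",
    pos = "numeric"
  )
)

setValidity("GenotypeMatrix", function(object) {
  S <- ncol(object@dosage)
  msg <- character()
  if ((nrow(object@dosage) > 0 && is.null(rownames(object@dosage))) ||
      (S > 0 && is.null(colnames(object@dosage))))
    msg <- c(msg, "dosage matrix needs sample and SNP dimnames")
  if (length(object@effectAllele) != S || length(object@otherAllele) != S)
    msg <- c(msg, "allele vectors must have one entry per SNP")
  if (length(object@chrom) != S || length(object@pos) != S)
    msg <- c(msg, "chrom/pos must have one entry per SNP")
  d <- object@dosage
  if (any(d < 0 | d > 2, na.rm = TRUE))
    msg <- c(msg, "dosages must lie in [0, 2]")
  ok <- is.na(object@effectAllele) | object@effectAllele %in% c("A", "C", "G", "T")
  ok2 <- is.na(object@otherAllele) | object@otherAllele %in% c("A", "C", "G", "T")
  if (!all(ok & ok2)) msg <- c(msg, "alleles must be A/C/G/T (or NA)")
  if (anyDuplicated(colnames(object@dosage))) msg <- c(msg, "duplicate SNP ids")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix object
#'
#' @param dosage numeric matrix, subjects in rows and SNPs in columns;
#'   rownames/colnames are used as sample and SNP ids (defaults generated
#'   when absent).
#' @param effectAllele,otherAllele per-SNP allele labels; NA allowed when the
#'   source format carries no allele metadata.
#' @param chrom,pos optional per-SNP genomic coordinates (1-based).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 1), 2, 2))
#' @export
GenotypeMatrix <- function(dosage, effectAllele = NULL, otherAllele = NULL,
                           chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  S <- ncol(dosage)
  if (is.null(effectAllele)) effectAllele <- rep(NA_character_, S)
  if (is.null(otherAllele)) otherAllele <- rep(NA_character_, S)
  if (is.null(chrom)) chrom <- rep(NA_character_, S)
  if (is.null(pos)) pos <- rep(NA_real_, S)
  new("GenotypeMatrix", dosage = dosage,
      effectAllele = as.character(effectAllele),
      otherAllele = as.character(otherAllele),
      chrom = as.character(chrom), pos = as.numeric(pos))
}

#' Per-gene eQTL weight set
#'
#' eQTL effect sizes used as SNP weights in the burden score, oriented to a
#' stated effect allele.
#'
#' @slot gene single gene identifier.
#' @slot snp character vector of SNP ids.
#' @slot effectAllele,otherAllele per-SNP allele labels (A/C/G/T).
#' @slot beta numeric eQTL effect sizes, one per SNP.
#'
#' @exportClass EqtlWeights
setClass("EqtlWeights",
  representation(
    gene = "character",
    snp = "character",
    effectAllele = "character",
    otherAllele = "character",
    beta = "numeric"
  )
)

setValidity("EqtlWeights", function(object) {
  S <- length(object@snp)
  msg <- character()
  if (length(object@gene) != 1L) msg <- c(msg, "gene must be a single id")
  if (length(object@beta) != S || length(object@effectAllele) != S ||
      length(object@otherAllele) != S)
    msg <- c(msg, "snp/alleles/beta lengths differ")
  if (anyDuplicated(object@snp)) msg <- c(msg, "duplicate SNP ids")
  if (any(!is.finite(object@beta))) msg <- c(msg, "betas must be finite")
  if (!all(object@effectAllele %in% c("A", "C", "G", "T")) ||
      !all(object@otherAllele %in% c("A", "C", "G", "T")))
    msg <- c(msg, "alleles must be A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' Construct an EqtlWeights object
#'
#' @param gene gene identifier.
#' @param snp SNP ids.
#' @param effectAllele,otherAllele allele labels the betas are oriented to.
#' @param beta eQTL effect sizes.
#' @return An [EqtlWeights-class] object.
#' @export
EqtlWeights <- function(gene, snp, effectAllele, otherAllele, beta) {
  new("EqtlWeights", gene = as.character(gene), snp = as.character(snp),
      effectAllele = toupper(as.character(effectAllele)),
      otherAllele = toupper(as.character(otherAllele)),
      beta = as.numeric(beta))
}

#' Fitted Cox proportional-hazards model
#'
#' Result of a maximum partial-likelihood fit, carrying everything the
#' SNP-set tests are built on: coefficients and their covariance, the linear
#' predictor, the Breslow baseline cumulative hazard, and martingale
#' residuals \eqn{r_i = d_i - \hat\Lambda_0(t_i) e^{\hat\eta_i}}.  The design
#' matrix, times, status and tie-handling choice are retained so that the
#' observed-information operator in the linear predictor can be rebuilt by
#' the kernel-machine score test.
#'
#' @slot coefficients named numeric vector.
#' @slot vcov coefficient covariance matrix.
#' @slot logLik maximized log partial likelihood.
#' @slot linearPredictor numeric n-vector (uncentered design times
#'   coefficients).
#' @slot baselineCumhaz data.frame with columns `time` and `cumhaz`: the
#'   Breslow step estimator at event times.
#' @slot martingaleResiduals numeric n-vector.
#' @slot converged logical flag.
#' @slot nIter Newton iterations used.
#' @slot design the fitted design matrix (may have zero columns).
#' @slot time,status the outcome the model was fitted to.
#' @slot ties tie handling used ("efron" or "breslow").
#'
#' @exportClass CoxFit
setClass("CoxFit",
  representation(
    coefficients = "numeric",
    vcov = "matrix",
    logLik = "numeric",
    linearPredictor = "numeric",
    baselineCumhaz = "data.frame",
    martingaleResiduals = "numeric",
    converged = "logical",
    nIter = "integer",
    design = "matrix",
    time = "numeric",
    status = "numeric",
    ties = "character"
  )
)

#' Variance-component score test result
#'
#' Quadratic-form statistic \eqn{Q = r^T G G^T r} (linear kernel) with the
#' eigenvalues of its chi-square-mixture null and the tail probability.
#'
#' @slot Q nonnegative statistic.
#' @slot eigenvalues nonincreasing positive mixture weights after truncation.
#' @slot pValue tail probability in (0, 1].
#' @slot tailMethod which tail approximation produced the p-value:
#'   "davies", "liu_moment", "monte_carlo", or "degenerate" when Q = 0 with
#'   an empty kernel.
#'
#' @exportClass KernelScoreResult
setClass("KernelScoreResult",
  representation(
    Q = "numeric",
    eigenvalues = "numeric",
    pValue = "numeric",
    tailMethod = "character"
  )
)

setValidity("KernelScoreResult", function(object) {
  msg <- character()
  if (object@Q < 0) msg <- c(msg, "Q must be nonnegative")
  if (length(object@eigenvalues) &&
      (any(object@eigenvalues <= 0) || is.unsorted(rev(object@eigenvalues))))
    msg <- c(msg, "eigenvalues must be positive and nonincreasing")
  if (object@pValue <= 0 || object@pValue > 1) msg <- c(msg, "p must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Joint-test combination result
#'
#' The three combinations of the burden component (p or chi-square statistic
#' U_theta) with the decorrelated variance-component result, plus the
#' quantities behind the optimal-rho search.
#'
#' @slot pFisher,pAdapt,pOptim combined p-values.
#' @slot rhoSelected grid value attaining the minimum component p.
#' @slot rhoGrid the rho grid searched.
#' @slot zTheta,zTau -2 log of the component p-values.
#' @slot tRho grid statistics rho*U_theta + (1-rho)*U_tau.
#'
#' @exportClass CombinationResult
setClass("CombinationResult",
  representation(
    pFisher = "numeric",
    pAdapt = "numeric",
    pOptim = "numeric",
    rhoSelected = "numeric",
    rhoGrid = "numeric",
    zTheta = "numeric",
    zTau = "numeric",
    tRho = "numeric"
  )
)
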