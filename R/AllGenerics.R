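#' Accessor generics
#'
#' Small accessor layer over the data containers so downstream code never
#' touches slots directly.
#'
#' @param object a package object.
#' @param x a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("effectAlleles", function(x) standardGeneric("effectAlleles"))

#' @rdname accessors
#' @export
setGeneric("otherAlleles", function(x) standardGeneric("otherAlleles"))

#' @rdname accessors
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname accessors
#' @export
setGeneric("missingness", function(x) standardGeneric("missingness"))

#' @rdname accessors
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname accessors
#' @export
setGeneric("eventStatus", function(x) standardGeneric("eventStatus"))

#' @rdname accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname accessors
#' @export
setGeneric("weightBetas", function(x) standardGeneric("weightBetas"))

#' @rdname accessors
#' @export
setGeneric("martingaleResiduals", function(x) standardGeneric("martingaleResiduals"))

#' @rdname accessors
#' @export
setGeneric("baselineCumhaz", function(x) standardGeneric("baselineCumhaz"))

#' @rdname accessors
#' @export
setGeneric("scoreStatistic", function(x) standardGeneric("scoreStatistic"))

#' @rdname accessors
#' @export
setGeneric("nullEigenvalues", function(x) standardGeneric("nullEigenvalues"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("tailMethod", function(x) standardGeneric("tailMethod"))

#' Subset a genotype matrix
#'
#' @param x a [GenotypeMatrix-class].
#' @param samples,snps identifiers or indices to keep (NULL = keep all).
#' @return a [GenotypeMatrix-class] restricted to the requested rows/columns.
#' @export
setGeneric("subsetGenotypes", function(x, samples = NULL, snps = NULL)
  standardGeneric("subsetGenotypes"))
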