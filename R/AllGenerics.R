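#' @rdname GenotypeMatrix
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeMatrix
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' @rdname LocalAncestryMatrix
#' @export
setGeneric("ancestryDosage", function(x) standardGeneric("ancestryDosage"))

#' @rdname LocalAncestryMatrix
#' @export
setGeneric("globalAncestry", function(x) standardGeneric("globalAncestry"))

#' @rdname KinshipMatrix
#' @export
setGeneric("kinship", function(x) standardGeneric("kinship"))

#' Per-SNP theta values of an Fst distribution
#' @param x a \linkS4class{FstDistribution}
#' @return numeric vector of per-SNP Weir-Cockerham theta values
#' @export
setGeneric("perSnpTheta", function(x) standardGeneric("perSnpTheta"))

#' Multi-locus (ratio-of-sums) Weir-Cockerham theta
#' @param x a \linkS4class{FstDistribution}
#' @export
setGeneric("multiLocusTheta", function(x) standardGeneric("multiLocusTheta"))

#' Qst pseudo-sample draws
#' @param x a \linkS4class{BootstrapResult} or \linkS4class{QstBootstrap}
#' @param cOverH2 ratio at which stored per-draw components are re-evaluated
#'   (QstBootstrap method only)
#' @export
setGeneric("qstDraws", function(x, ...) standardGeneric("qstDraws"))

#' Fst pseudo-sample draws
#' @param x a \linkS4class{BootstrapResult}
#' @export
setGeneric("fstDraws", function(x) standardGeneric("fstDraws"))

#' Empirical p-value of the divergence test
#' @param x a \linkS4class{BootstrapResult}
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' Critical c/h2 ratio of a sensitivity curve
#' @param x a \linkS4class{SensitivityCurve}
#' @return the smallest grid ratio at which the lower Qst bound meets the
#'   upper Fst bound, or \code{NA} when not reached within the grid
#' @export
setGeneric("criticalRatio", function(x) standardGeneric("criticalRatio"))
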