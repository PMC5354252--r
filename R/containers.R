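## Constructors, accessors and show methods for the data containers.

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix of alternate-allele dosages (0/1/2, NA
#'   allowed), SNPs in rows and individuals in columns. A transposed matrix
#'   (individuals x SNPs) is accepted when row/column names disambiguate via
#'   \code{population} length.
#' @param population character/factor vector of population labels, one per
#'   individual (column).
#' @param snpIds,individualIds optional ids; defaults taken from dimnames or
#'   generated.
#' @return a \linkS4class{GenotypeMatrix}
#' @examples
#' g <- GenotypeMatrix(matrix(c(0, 1, 2, 1), 2), population = c("A", "B"))
#' population(g)
#' @export
GenotypeMatrix <- function(dosage, population, snpIds = NULL,
                           individualIds = NULL) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != length(population) && nrow(dosage) == length(population))
    dosage <- t(dosage)
  if (ncol(dosage) != length(population))
    stop("'population' must have one label per individual")
  if (is.null(snpIds))
    snpIds <- if (!is.null(rownames(dosage))) rownames(dosage) else
      paste0("snp", seq_len(nrow(dosage)))
  if (is.null(individualIds))
    individualIds <- if (!is.null(colnames(dosage))) colnames(dosage) else
      paste0("ind", seq_len(ncol(dosage)))
  dimnames(dosage) <- list(snpIds, individualIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    colData = S4Vectors::DataFrame(population = as.character(population),
                                   row.names = individualIds))
  new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix
#' @export
setMethod("dosage", "GenotypeMatrix", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeMatrix
#' @export
setMethod("population", "GenotypeMatrix", function(x)
  as.character(SummarizedExperiment::colData(x)$population))

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object), "SNPs x", ncol(object),
      "individuals\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(population(object))),
                    table(population(object))), collapse = ", "), "\n")
})

#' Construct a LocalAncestryMatrix
#'
#' @param ancestry numeric matrix of local-ancestry dosages (0/1/2), SNPs in
#'   rows and individuals in columns.
#' @param snpIds,individualIds optional ids.
#' @return a \linkS4class{LocalAncestryMatrix}
#' @export
LocalAncestryMatrix <- function(ancestry, snpIds = NULL,
                                individualIds = NULL) {
  ancestry <- as.matrix(ancestry)
  if (is.null(snpIds))
    snpIds <- if (!is.null(rownames(ancestry))) rownames(ancestry) else
      paste0("snp", seq_len(nrow(ancestry)))
  if (is.null(individualIds))
    individualIds <- if (!is.null(colnames(ancestry))) colnames(ancestry) else
      paste0("ind", seq_len(ncol(ancestry)))
  dimnames(ancestry) <- list(snpIds, individualIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ancestry = ancestry))
  colnames(se) <- individualIds
  new("LocalAncestryMatrix", se)
}

#' @rdname LocalAncestryMatrix
#' @export
setMethod("ancestryDosage", "LocalAncestryMatrix", function(x)
  SummarizedExperiment::assay(x, "ancestry"))

#' @rdname LocalAncestryMatrix
#' @export
setMethod("globalAncestry", "LocalAncestryMatrix", function(x)
  colMeans(SummarizedExperiment::assay(x, "ancestry")) / 2)

setMethod("show", "LocalAncestryMatrix", function(object) {
  q <- globalAncestry(object)
  cat("LocalAncestryMatrix:", nrow(object), "SNPs x", ncol(object),
      "individuals\n")
  cat(sprintf("global ancestry: mean %.3f, range [%.3f, %.3f]\n",
              mean(q), min(q), max(q)))
})

#' Construct a KinshipMatrix
#'
#' @param K square symmetric numeric matrix
#' @param source provenance tag: "genotype", "local-ancestry" or "external"
#' @param nMarkers number of markers behind the construction
#' @export
KinshipMatrix <- function(K, source = "external", nMarkers = NA_integer_) {
  K <- as.matrix(K)
  K <- (K + t(K)) / 2   # enforce exact symmetry against rounding
  new("KinshipMatrix", kinship = K, source = source,
      nMarkers = as.integer(nMarkers))
}

#' @rdname KinshipMatrix
#' @export
setMethod("kinship", "KinshipMatrix", function(x) x@kinship)

setMethod("dim", "KinshipMatrix", function(x) dim(x@kinship))

setMethod("show", "KinshipMatrix", function(object) {
  K <- object@kinship
  cat(sprintf("KinshipMatrix (%s): %d individuals, %s markers\n",
              object@source, nrow(K),
              ifelse(is.na(object@nMarkers), "?", object@nMarkers)))
  cat(sprintf("mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(K)), mean(K[upper.tri(K)])))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents [%s]: a = %d populations, n = %d\n",
              object@trait, object@nPops, object@nUsed))
  cat(sprintf("  MSB = %.4g  MSW = %.4g  n0 = %.3f\n",
              object@MSB, object@MSW, object@n0))
  cat(sprintf("  sigma2_pb = %.4g%s  sigma2_pw = %.4g\n", object@sigma2pb,
              ifelse(object@clamped, " (clamped)", ""), object@sigma2pw))
  cat(sprintf("  population effect: F = %.3f, p = %.3g\n",
              object@Fstat, object@pValue))
})

#' @rdname perSnpTheta
#' @export
setMethod("perSnpTheta", "FstDistribution", function(x) x@perSnp$theta)

#' @rdname multiLocusTheta
#' @export
setMethod("multiLocusTheta", "FstDistribution", function(x) x@multiLocus)

setMethod("show", "FstDistribution", function(object) {
  cat(sprintf("FstDistribution: %d SNPs used (%d excluded)\n",
              object@nUsed, object@nExcluded))
  cat(sprintf("multi-locus theta = %.4f; per-SNP median = %.4f\n",
              object@multiLocus, median(object@perSnp$theta)))
})

#' @rdname qstDraws
#' @export
setMethod("qstDraws", "QstBootstrap", function(x, cOverH2 = 1) {
  qstFromComponents(x@sigma2pbDraws, x@sigma2pwDraws, cOverH2)
})

#' @rdname qstDraws
#' @export
setMethod("qstDraws", "BootstrapResult", function(x, ...) x@qstDraws)

#' @rdname fstDraws
#' @export
setMethod("fstDraws", "BootstrapResult", function(x) x@fstDraws)

#' @rdname empiricalP
#' @export
setMethod("empiricalP", "BootstrapResult", function(x) x@empiricalP)

setMethod("show", "QstBootstrap", function(object) {
  cat(sprintf("QstBootstrap [%s]: %d stratified pseudo-samples (seed %d)\n",
              object@trait, object@nBoot, object@seed))
  q <- qstDraws(object)
  cat(sprintf("Qst draws at c/h2 = 1: median %.3f [%.3f, %.3f]\n",
              median(q), quantile(q, 0.025), quantile(q, 0.975)))
})

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("Qst-Fst divergence test [%s]\n", object@trait))
  cat(sprintf("  observed Qst = %.3f (c/h2 = 1), %d pseudo-samples\n",
              object@observedQst, object@nBoot))
  cat(sprintf("  empirical p %s%.4g\n",
              ifelse(object@pIsUpperBound, "< ", "= "),
              ifelse(object@pIsUpperBound, 1 / object@nBoot,
                     object@empiricalP)))
})

#' @rdname criticalRatio
#' @export
setMethod("criticalRatio", "SensitivityCurve", function(x) x@critical)

setMethod("show", "SensitivityCurve", function(object) {
  rng <- range(object@curve$ratio)
  cat(sprintf("SensitivityCurve [%s]: c/h2 grid [%g, %g], %d points\n",
              object@trait, rng[1], rng[2], nrow(object@curve)))
  if (object@criticalAboveMax) {
    cat(sprintf("critical c/h2 value: > %g (not reached within grid)\n",
                rng[2]))
  } else {
    cat(sprintf("critical c/h2 value: %g\n", object@critical))
  }
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf("%s = %.3f (SE %.3f), n = %d%s\n", object@kind, object@h2,
              object@se, object@n,
              ifelse(object@boundary, " [boundary estimate]", "")))
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g, REML logLik = %.2f\n",
              object@sigmaG2, object@sigmaE2, object@logLik))
  cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("Kinship-LMM association: %s ~ %s (n = %d)\n",
              object@trait, object@climateVar, object@n))
  cat(sprintf("  slope = %.4g  SE = %.4g  T = %.2f  LRT = %.2f  p = %.3g\n",
              object@slope, object@se, object@tStat, object@lrt,
              object@pValue))
})

## as.data.frame helpers used by the pipeline writers

#' @export
#' @rdname criticalRatio
setMethod("as.data.frame", "SensitivityCurve",
          function(x, row.names = NULL, optional = FALSE, ...) x@curve)
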