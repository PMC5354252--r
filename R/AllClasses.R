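#' @import methods
#' @importFrom stats anova aov as.formula complete.cases cor dist ecdf lm
#'   model.matrix na.omit optimize pchisq pf pnorm qnorm quantile rbeta
#'   rbinom rgeom rnorm runif sd setNames var median ks.test coef logLik
#'   resid rexp prcomp ave aggregate .lm.fit
#' @importFrom utils read.delim write.table head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## Central data containers
## ---------------------------------------------------------------------------

#' Genotype dosage matrix with population labels
#'
#' A \linkS4class{SummarizedExperiment} holding a SNP-by-individual dosage
#' assay (counts of the alternate allele, 0/1/2, \code{NA} allowed) with a
#' mandatory \code{population} column in \code{colData}.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}; the single
#'   assay is named \code{"dosage"}.
#' @seealso [GenotypeMatrix()] for the constructor, [wcTheta()], [grm()]
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!is.numeric(d))
    return("dosage assay must be numeric")
  bad <- d[!is.na(d)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    return("dosages must lie in [0, 2]")
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain a 'population' column")
  if (anyNA(SummarizedExperiment::colData(object)$population))
    return("every individual needs a population label")
  TRUE
})

#' Local-ancestry dosage matrix
#'
#' A \linkS4class{SummarizedExperiment} with a SNP-by-individual assay
#' \code{"ancestry"}: the number of chromosome copies (0/1/2) derived from one
#' designated parental population at each SNP of an admixed individual.
#' Global ancestry is the per-individual mean dosage divided by 2.
#'
#' @seealso [LocalAncestryMatrix()], [ancestryGrm()], [globalAncestry()]
#' @exportClass LocalAncestryMatrix
setClass("LocalAncestryMatrix", contains = "SummarizedExperiment")

setValidity("LocalAncestryMatrix", function(object) {
  if (!"ancestry" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ancestry' is required")
  a <- SummarizedExperiment::assay(object, "ancestry")
  if (anyNA(a) || any(a < 0) || any(a > 2))
    return("ancestry dosages must lie in [0, 2] with no missing values")
  TRUE
})

#' Kinship (genetic relationship) matrix
#'
#' Square symmetric relatedness matrix over individuals, built either from
#' standardized genotypes ([grm()]) or from standardized local-ancestry
#' dosages ([ancestryGrm()]).
#'
#' @slot kinship numeric matrix, symmetric, dimnames = individual ids
#' @slot source one of \code{"genotype"}, \code{"local-ancestry"},
#'   \code{"external"}
#' @slot nMarkers number of markers that entered the construction
#' @exportClass KinshipMatrix
setClass("KinshipMatrix",
  representation(kinship = "matrix", source = "character",
                 nMarkers = "integer"))

setValidity("KinshipMatrix", function(object) {
  K <- object@kinship
  if (nrow(K) != ncol(K)) return("kinship matrix must be square")
  if (anyNA(K)) return("kinship matrix contains NA/NaN")
  if (max(abs(K - t(K))) > 1e-8) return("kinship matrix must be symmetric")
  TRUE
})

## ---------------------------------------------------------------------------
## Result containers
## ---------------------------------------------------------------------------

#' ANOVA variance components behind a Qst estimate
#'
#' Moment estimators from the population-effect linear model: \code{MSB} is
#' the marginal mean square for population given the covariates, \code{MSW}
#' the residual mean square, \code{n0} the effective per-population size
#' \eqn{n_0 = (\sum n_i - \sum n_i^2 / \sum n_i)/(a-1)},
#' \eqn{\sigma^2_{pw} = MSW} and
#' \eqn{\sigma^2_{pb} = (MSB - MSW)/n_0} (clamped at zero).
#'
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(trait = "character", nPops = "integer", ni = "integer",
                 n0 = "numeric", MSB = "numeric", MSW = "numeric",
                 sigma2pb = "numeric", sigma2pw = "numeric",
                 clamped = "logical", Fstat = "numeric", pValue = "numeric",
                 nUsed = "integer", nDropped = "integer",
                 covariates = "character"))

setValidity("VarianceComponents", function(object) {
  if (object@n0 <= 0) return("n0 must be positive")
  if (object@sigma2pb < 0) return("sigma2pb must be >= 0 after clamping")
  if (object@MSW < 0) return("MSW must be non-negative")
  TRUE
})

#' Per-SNP and multi-locus Weir-Cockerham theta
#'
#' @slot perSnp data.frame with columns \code{snp}, \code{a} (among-population
#'   variance component), \code{d} (total \code{a+b+c}), \code{theta}
#' @slot multiLocus ratio-of-sums estimate \eqn{\sum a / \sum(a+b+c)}
#' @slot nUsed,nExcluded SNP counts (excluded = monomorphic or undefined)
#' @exportClass FstDistribution
setClass("FstDistribution",
  representation(perSnp = "data.frame", multiLocus = "numeric",
                 nUsed = "integer", nExcluded = "integer"))

setValidity("FstDistribution", function(object) {
  need <- c("snp", "a", "d", "theta")
  if (!all(need %in% names(object@perSnp)))
    return("perSnp needs columns snp, a, d, theta")
  if (object@nUsed != nrow(object@perSnp))
    return("nUsed must equal nrow(perSnp)")
  TRUE
})

#' Stratified-bootstrap Qst draws for one trait
#'
#' Holds the per-draw variance components so that Qst can be re-evaluated at
#' any c/h2 ratio without re-resampling.
#'
#' @exportClass QstBootstrap
setClass("QstBootstrap",
  representation(trait = "character", observed = "VarianceComponents",
                 sigma2pbDraws = "numeric", sigma2pwDraws = "numeric",
                 nBoot = "integer", seed = "integer", strata = "data.frame"))

#' Paired bootstrap Qst-Fst divergence test result
#'
#' @slot qstDraws,fstDraws paired pseudo-sample values (length \code{nBoot})
#' @slot empiricalP proportion of \code{qstDraws - fstDraws} below zero; when
#'   the proportion is exactly zero it is reported as bounded above by
#'   \code{1/nBoot} and \code{pIsUpperBound} is \code{TRUE}
#' @exportClass BootstrapResult
setClass("BootstrapResult",
  representation(trait = "character", observedQst = "numeric",
                 qstDraws = "numeric", fstDraws = "numeric",
                 empiricalP = "numeric", pIsUpperBound = "logical",
                 nBoot = "integer", seed = "integer"))

setValidity("BootstrapResult", function(object) {
  if (length(object@qstDraws) != length(object@fstDraws))
    return("qst and fst draws must be paired (equal length)")
  if (length(object@qstDraws) != object@nBoot)
    return("draw vectors must have length nBoot")
  if (object@empiricalP < 0 || object@empiricalP > 1)
    return("empirical p must lie in [0, 1]")
  TRUE
})

#' c/h2 sensitivity curve with critical-value detection
#'
#' @slot curve data.frame over the ratio grid with Qst / Fst medians and
#'   central-interval bounds
#' @slot critical smallest grid ratio at which the lower Qst bound meets the
#'   upper Fst bound; \code{NA} (flagged \code{criticalAboveMax}) if never
#' @exportClass SensitivityCurve
setClass("SensitivityCurve",
  representation(trait = "character", curve = "data.frame",
                 critical = "numeric", criticalAboveMax = "logical",
                 ciLevel = "numeric"))

#' Single-component REML heritability estimate
#'
#' @slot h2 proportion of phenotypic variance attributed to the kinship
#'   component; \code{kind} is \code{"h_g2"} (genotype GRM) or \code{"h_y2"}
#'   (local-ancestry GRM, the estimator of the between-population
#'   heritability c)
#' @exportClass HeritabilityEstimate
setClass("HeritabilityEstimate",
  representation(h2 = "numeric", se = "numeric", sigmaG2 = "numeric",
                 sigmaE2 = "numeric", logLik = "numeric", kind = "character",
                 n = "integer", covariates = "character",
                 boundary = "logical"))

setValidity("HeritabilityEstimate", function(object) {
  if (object@h2 < 0 || object@h2 > 1) return("h2 must lie in [0, 1]")
  if (!is.na(object@se) && object@se <= 0) return("SE must be positive")
  TRUE
})

#' Kinship-LMM phenotype-climate association result
#'
#' @slot lrt likelihood-ratio statistic, full vs climate-dropped model (ML
#'   fits); \code{pValue} from a 1-df chi-square
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(trait = "character", climateVar = "character",
                 slope = "numeric", se = "numeric", tStat = "numeric",
                 lrt = "numeric", pValue = "numeric", n = "integer",
                 covariates = "character", h2 = "numeric"))

setValidity("AssociationResult", function(object) {
  if (object@lrt < -1e-8) return("LRT statistic must be non-negative")
  if (object@pValue <= 0 || object@pValue > 1)
    return("p-value must lie in (0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Simulation configurations
## ---------------------------------------------------------------------------

#' Configuration for the discrete-population simulator
#'
#' Bundles the study-design parameters of a Balding-Nichols style simulation:
#' K drifted populations with target multi-locus Fst, polygenic traits with
#' specified between/within additive variances, within-population
#' heritability h2 and between-population heritability c, and sex/age/BMI
#' covariate effects.
#'
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nPops = "integer", nPerPop = "integer", nSnps = "integer",
                 targetFst = "numeric", mafRange = "numeric",
                 sigma2gb = "numeric", sigma2gw = "numeric",
                 h2 = "numeric", c = "numeric",
                 covariateEffects = "numeric", betweenMode = "character",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nPops < 1L || any(object@nPerPop < 1L) || object@nSnps < 1L)
    return("all counts must be positive")
  if (length(object@nPerPop) != object@nPops)
    return("nPerPop must have one entry per population")
  if (object@targetFst < 0 || object@targetFst >= 1)
    return("targetFst must lie in [0, 1)")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
    return("mafRange must be an interval within (0, 0.5]")
  if (mr[1] == mr[2] && mr[1] == 0)
    return("degenerate mafRange at 0")
  if (object@h2 < 0 || object@h2 > 1) return("h2 must lie in [0, 1]")
  if (object@c < 0 || object@c > 1) return("c must lie in [0, 1]")
  if (object@c > 0 && object@sigma2gb == 0)
    return("c > 0 requires sigma2gb > 0")
  if (!object@betweenMode %in% c("exact", "drift"))
    return("betweenMode must be 'exact' or 'drift'")
  if (!all(c("sex", "age", "bmi") %in% names(object@covariateEffects)))
    return("covariateEffects needs named entries sex, age, bmi")
  TRUE
})

#' Configuration for the admixed-cohort simulator
#'
#' @exportClass AdmixSimConfig
setClass("AdmixSimConfig",
  representation(nInd = "integer", nSnps = "integer",
                 ancestryMean = "numeric", tractMeanSnps = "numeric",
                 hy2Target = "numeric", parentalFst = "numeric",
                 seed = "integer"))

setValidity("AdmixSimConfig", function(object) {
  if (object@nInd < 2L || object@nSnps < 1L)
    return("all counts must be positive (nInd >= 2)")
  if (object@ancestryMean <= 0 || object@ancestryMean >= 1)
    return("ancestryMean must lie in (0, 1)")
  if (object@tractMeanSnps < 1)
    return("tractMeanSnps must be >= 1")
  if (object@hy2Target < 0 || object@hy2Target > 1)
    return("hy2Target must lie in [0, 1]")
  TRUE
})
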