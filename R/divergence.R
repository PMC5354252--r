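## Stratified-bootstrap Qst-Fst comparison: empirical p-values against the
## genome-wide per-SNP theta distribution, Bonferroni reporting, and c/h2
## sensitivity curves with critical-value detection.

## fast marginal ANOVA on a pre-built design: returns c(sigma2pb, sigma2pw)
## given responses y and the full/reduced model matrices
componentsFit <- function(y, Xfull, Xred, dfPop, n0) {
  fitF <- .lm.fit(Xfull, y)
  fitR <- .lm.fit(Xred, y)
  rssF <- sum(fitF$residuals^2)
  MSB <- (sum(fitR$residuals^2) - rssF) / dfPop
  MSW <- rssF / (length(y) - fitF$rank)
  c(max((MSB - MSW) / n0, 0), MSW)
}

#' Stratified bootstrap of the Qst variance components
#'
#' Generates pseudo-samples by resampling individuals with replacement
#' within population-by-sex strata, so that the number of males and females
#' in each population is unchanged in every draw, and recomputes the
#' covariate-adjusted variance components for each pseudo-sample. The
#' per-draw components are stored so that Qst can later be re-evaluated at
#' any c/h2 ratio without re-resampling.
#'
#' @param pheno phenotype data.frame (id, population, sex, covariates,
#'   trait columns)
#' @param trait trait column name
#' @param covariates covariate columns for the variance-component model
#' @param nBoot number of pseudo-samples (default 10000)
#' @param seed integer seed
#' @return a \linkS4class{QstBootstrap}
#' @export
bootstrapQst <- function(pheno, trait, covariates = c("sex", "age", "bmi"),
                         nBoot = 10000, seed = 1) {
  observed <- varianceComponents(pheno, trait, covariates)
  keep <- complete.cases(pheno[, c("population", trait, covariates),
                               drop = FALSE])
  d <- pheno[keep, , drop = FALSE]
  d$population <- factor(d$population)

  strataVars <- c("population", intersect("sex", names(d)))
  strata <- interaction(d[strataVars], drop = TRUE)
  sizes <- table(strata)
  if (any(sizes == 0))
    stop("empty stratum: ", paste(names(sizes)[sizes == 0], collapse = ", "))
  idxByStratum <- split(seq_len(nrow(d)), strata)

  covTerms <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  Xfull <- model.matrix(as.formula(paste("~", covTerms, "+ population")), d)
  Xred <- model.matrix(as.formula(paste("~", covTerms)), d)
  y <- d[[trait]]
  a <- nlevels(d$population)
  ni <- as.integer(table(d$population))
  n <- sum(ni)
  n0 <- (n - sum(ni^2) / n) / (a - 1)

  set.seed(as.integer(seed))
  comp <- matrix(NA_real_, nBoot, 2)
  for (b in seq_len(nBoot)) {
    idx <- unlist(lapply(idxByStratum, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    comp[b, ] <- componentsFit(y[idx], Xfull[idx, , drop = FALSE],
                               Xred[idx, , drop = FALSE], a - 1L, n0)
  }
  new("QstBootstrap", trait = trait, observed = observed,
      sigma2pbDraws = comp[, 1], sigma2pwDraws = comp[, 2],
      nBoot = as.integer(nBoot), seed = as.integer(seed),
      strata = data.frame(stratum = names(sizes),
                          size = as.integer(sizes)))
}

#' Qst-Fst divergence test
#'
#' Pairs each bootstrap Qst pseudo-sample with an Fst value drawn (with
#' replacement) from the realized genome-wide distribution, forms the
#' per-pair difference Qst - Fst, and reports the empirical p-value as the
#' proportion of differences below zero. Under the drift null Qst - Fst is
#' centred at zero; large observed Qst makes negative differences rare.
#' A zero proportion is reported as bounded above by \code{1/nBoot} rather
#' than as exactly zero.
#'
#' @param qstBoot a \linkS4class{QstBootstrap}
#' @param fstDist a \linkS4class{FstDistribution}
#' @param cOverH2 heritability ratio at which Qst draws are evaluated
#'   (default 1)
#' @param fstMode \code{"single-snp"} (default) draws one per-SNP theta per
#'   pseudo-sample; \code{"multilocus"} recomputes a ratio-of-sums theta
#'   from a resampled SNP set per pseudo-sample (much heavier)
#' @param seed seed for the Fst draws (default: the bootstrap seed + 1)
#' @return a \linkS4class{BootstrapResult}
#' @export
qstFstTest <- function(qstBoot, fstDist, cOverH2 = 1,
                       fstMode = c("single-snp", "multilocus"),
                       seed = qstBoot@seed + 1L) {
  stopifnot(is(qstBoot, "QstBootstrap"), is(fstDist, "FstDistribution"))
  fstMode <- match.arg(fstMode)
  if (fstDist@nUsed < 1L) stop("empty Fst distribution")
  nBoot <- qstBoot@nBoot
  qst <- qstDraws(qstBoot, cOverH2 = cOverH2)

  set.seed(as.integer(seed))
  fst <- if (fstMode == "single-snp") {
    sample(fstDist@perSnp$theta, nBoot, replace = TRUE)
  } else {
    M <- fstDist@nUsed
    vapply(seq_len(nBoot), function(b) {
      ix <- sample.int(M, M, replace = TRUE)
      sum(fstDist@perSnp$a[ix]) / sum(fstDist@perSnp$d[ix])
    }, numeric(1))
  }

  pRaw <- mean(qst - fst < 0)
  upperBound <- pRaw == 0
  obs <- qstValue(qstBoot@observed, cOverH2)$qst
  new("BootstrapResult", trait = qstBoot@trait, observedQst = obs,
      qstDraws = qst, fstDraws = fst,
      empiricalP = if (upperBound) 1 / nBoot else pRaw,
      pIsUpperBound = upperBound, nBoot = nBoot, seed = as.integer(seed))
}

#' Bonferroni significance report over a family of divergence tests
#'
#' Flags a trait as showing accelerated divergence iff its empirical
#' p-value is strictly below \code{alpha / nTests} (default 0.05/7 = 0.0071
#' for a seven-trait nose-shape family).
#'
#' @param pValues named numeric vector of empirical p-values in [0, 1]
#' @param alpha family-wise level
#' @param nTests number of tests in the family
#' @return data.frame: trait, p, threshold, accelerated
#' @export
bonferroniReport <- function(pValues, alpha = 0.05, nTests = 7) {
  if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
  thr <- alpha / nTests
  data.frame(trait = if (is.null(names(pValues)))
               paste0("trait", seq_along(pValues)) else names(pValues),
             p = as.numeric(pValues), threshold = thr,
             accelerated = as.numeric(pValues) < thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' c/h2 sensitivity curve and critical-value detection
#'
#' Re-evaluates the stored bootstrap variance components at each ratio r of
#' the grid (no re-resampling: Qst(r) is a deterministic rescaling of each
#' draw's components) and locates the critical value: the smallest grid
#' ratio at which the lower central-interval bound of Qst meets the upper
#' bound of the Fst draws. A curve that never crosses within the grid is
#' flagged as "> max(grid)".
#'
#' @param qstBoot a \linkS4class{QstBootstrap}
#' @param fst a \linkS4class{BootstrapResult} (its paired Fst draws are
#'   used), a \linkS4class{FstDistribution} (per-SNP thetas), or a numeric
#'   vector of Fst draws
#' @param grid increasing positive ratio grid (default 0.01..1 by 0.01)
#' @param ciLevel central interval mass (default 0.95)
#' @return a \linkS4class{SensitivityCurve}
#' @export
sensitivityCurve <- function(qstBoot, fst, grid = seq(0.01, 1, by = 0.01),
                             ciLevel = 0.95) {
  stopifnot(is(qstBoot, "QstBootstrap"))
  if (!length(grid) || any(diff(grid) <= 0) || any(grid <= 0))
    stop("grid must be increasing and positive")
  fstDraws <- if (is(fst, "BootstrapResult")) fst@fstDraws
    else if (is(fst, "FstDistribution")) fst@perSnp$theta
    else as.numeric(fst)
  alpha <- (1 - ciLevel) / 2
  fq <- quantile(fstDraws, c(alpha, 0.5, 1 - alpha), names = FALSE)

  qs <- vapply(grid, function(r) {
    quantile(qstFromComponents(qstBoot@sigma2pbDraws,
                               qstBoot@sigma2pwDraws, r),
             c(alpha, 0.5, 1 - alpha), names = FALSE)
  }, numeric(3))
  curve <- data.frame(ratio = grid,
                      qstLower = qs[1, ], qstMedian = qs[2, ],
                      qstUpper = qs[3, ],
                      fstLower = fq[1], fstMedian = fq[2], fstUpper = fq[3])
  hit <- which(curve$qstLower >= curve$fstUpper)
  aboveMax <- !length(hit)
  new("SensitivityCurve", trait = qstBoot@trait, curve = curve,
      critical = if (aboveMax) NA_real_ else grid[hit[1]],
      criticalAboveMax = aboveMax, ciLevel = ciLevel)
}
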