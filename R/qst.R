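## Qst from covariate-adjusted phenotypic variance components.
##
## The estimand is Qst = sigma2_gb / (sigma2_gb + 2 sigma2_gw), the
## between-population share of additive genetic variance.  From phenotypes it
## is computed through the phenotypic components and the ratio r = c/h2:
##   Qst(r) = r sigma2_pb / (r sigma2_pb + 2 sigma2_pw).

#' Phenotypic variance components across populations
#'
#' Fits a linear model with population as a fixed effect and optional
#' covariates, and converts the mean squares into the among- and
#' within-population phenotypic variance components:
#' \deqn{n_0 = \frac{1}{a-1}\left(\sum_i n_i - \frac{\sum_i n_i^2}{\sum_i n_i}\right)}
#' \deqn{\hat\sigma^2_{pw} = MSW, \qquad \hat\sigma^2_{pb} = \frac{MSB - MSW}{n_0}}
#' where \code{MSB} is the marginal (type-II) mean square for the population
#' effect given the covariates and \code{MSW} the residual mean square.
#' A negative \eqn{\hat\sigma^2_{pb}} is clamped to zero (and flagged):
#' variances cannot be negative, and clamping keeps Qst well defined.
#'
#' Rows with a missing trait or covariate value are dropped listwise; the
#' count is recorded in the result.
#'
#' @param pheno data.frame with one row per individual, containing a
#'   \code{population} column, the trait column, and any covariate columns.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (default
#'   \code{c("sex", "age", "bmi")}); use \code{character(0)} for a plain
#'   one-way ANOVA.
#' @return a \linkS4class{VarianceComponents}
#' @examples
#' d <- data.frame(population = rep(c("A", "B"), each = 3), y = c(1:3, 4:6))
#' varianceComponents(d, "y", covariates = character(0))
#' @seealso [qstValue()]
#' @export
varianceComponents <- function(pheno, trait,
                               covariates = c("sex", "age", "bmi")) {
  stopifnot(is.data.frame(pheno))
  if (!"population" %in% names(pheno))
    stop("'pheno' must contain a 'population' column")
  missingCols <- setdiff(c(trait, covariates), names(pheno))
  if (length(missingCols))
    stop("column(s) not found: ", paste(missingCols, collapse = ", "))

  keep <- complete.cases(pheno[, c("population", trait, covariates),
                               drop = FALSE])
  nDropped <- sum(!keep)
  d <- pheno[keep, , drop = FALSE]
  d$population <- factor(d$population)
  a <- nlevels(d$population)
  if (a < 2L) stop("need at least 2 populations")
  ni <- as.integer(table(d$population))
  if (any(ni < 2L)) stop("every population needs at least 2 individuals")

  y <- d[[trait]]
  covTerms <- if (length(covariates))
    paste(covariates, collapse = " + ") else "1"
  full <- lm(as.formula(paste("y ~", covTerms, "+ population")), data = d)
  reduced <- lm(as.formula(paste("y ~", covTerms)), data = d)
  if (full$df.residual < 1L) stop("zero residual degrees of freedom")

  rssFull <- sum(resid(full)^2)
  ssPop <- sum(resid(reduced)^2) - rssFull   # marginal SS for population
  dfPop <- a - 1L
  MSB <- ssPop / dfPop
  MSW <- rssFull / full$df.residual

  n <- sum(ni)
  n0 <- (n - sum(ni^2) / n) / (a - 1)
  sigma2pb <- (MSB - MSW) / n0
  clamped <- sigma2pb < 0
  if (clamped) {
    message("negative among-population variance estimate clamped to 0 for '",
            trait, "'")
    sigma2pb <- 0
  }
  Fstat <- MSB / MSW
  pValue <- pf(Fstat, dfPop, full$df.residual, lower.tail = FALSE)

  new("VarianceComponents", trait = trait, nPops = a, ni = ni, n0 = n0,
      MSB = MSB, MSW = MSW, sigma2pb = sigma2pb, sigma2pw = MSW,
      clamped = clamped, Fstat = Fstat, pValue = pValue,
      nUsed = as.integer(n), nDropped = as.integer(nDropped),
      covariates = as.character(covariates))
}

## Vectorized Qst(r) from stored components; shared by qstValue, the
## bootstrap and the sensitivity curve (one code path for Eq rescaling).
qstFromComponents <- function(sigma2pb, sigma2pw, cOverH2 = 1) {
  num <- cOverH2 * sigma2pb
  den <- num + 2 * sigma2pw
  out <- ifelse(den > 0, num / den, 0)
  unname(out)
}

#' Qst at a given c/h2 ratio
#'
#' Evaluates \eqn{Qst(r) = r\,\sigma^2_{pb} / (r\,\sigma^2_{pb} + 2\sigma^2_{pw})}
#' with \eqn{r = c/h^2}. With no prior information on the heritability ratio
#' the conventional choice is \code{cOverH2 = 1}, under which the statistic
#' equals the phenotypic-variance Qst (sometimes called Pst).
#'
#' @param vc a \linkS4class{VarianceComponents}
#' @param cOverH2 positive ratio of between- to within-population
#'   heritability (default 1)
#' @return named list with \code{qst}, \code{cOverH2}, \code{trait}
#' @examples
#' d <- data.frame(population = rep(c("A", "B"), each = 3), y = c(1:3, 4:6))
#' vc <- varianceComponents(d, "y", covariates = character(0))
#' qstValue(vc)$qst   # 4.1667 / 6.1667
#' @export
qstValue <- function(vc, cOverH2 = 1) {
  stopifnot(is(vc, "VarianceComponents"))
  if (!is.numeric(cOverH2) || any(cOverH2 <= 0))
    stop("cOverH2 must be positive")
  list(qst = qstFromComponents(vc@sigma2pb, vc@sigma2pw, cOverH2),
       cOverH2 = cOverH2, trait = vc@trait)
}
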