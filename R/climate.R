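## Humidity derivation and kinship-corrected phenotype-climate association.

#' Saturation vapor pressure (Magnus form)
#'
#' \eqn{e_s(T) = 6.1094 \exp(17.625 T / (T + 243.04))} hPa, for air
#' temperature T in degrees Celsius.
#'
#' @param T temperature in deg C (must exceed -243.04)
#' @return saturation vapor pressure in hPa
#' @examples
#' saturationVaporPressure(0)    # 6.1094
#' saturationVaporPressure(20)   # 23.34
#' @export
saturationVaporPressure <- function(T) {
  if (any(T <= -243.04)) stop("temperature at or below -243.04 degC")
  6.1094 * exp(17.625 * T / (T + 243.04))
}

#' Relative humidity from vapor pressure and temperature
#'
#' \eqn{RH = 100\, e / e_s(T)} percent, capped at 100 (with a warning) when
#' the supplied vapor pressure exceeds saturation.
#'
#' @param e vapor pressure in hPa (>= 0)
#' @param T temperature in deg C
#' @return relative humidity in percent
#' @export
relativeHumidity <- function(e, T) {
  if (any(e < 0)) stop("vapor pressure must be non-negative")
  rh <- 100 * e / saturationVaporPressure(T)
  if (any(rh > 100 + 1e-9)) {
    warning("vapor pressure above saturation; relative humidity capped at 100")
    rh <- pmin(rh, 100)
  }
  rh
}

#' Absolute humidity from vapor pressure and temperature
#'
#' Water-vapor density by the ideal gas law with
#' \eqn{R_v = 461.5\,J\,kg^{-1}K^{-1}}:
#' \eqn{AH = 216.7\, e / (T + 273.15)} g/m3 for e in hPa and T in deg C.
#'
#' @param e vapor pressure in hPa (>= 0)
#' @param T temperature in deg C
#' @return absolute humidity in g/m3
#' @examples
#' absoluteHumidity(10, 20)  # 7.392
#' @export
absoluteHumidity <- function(e, T) {
  if (any(e < 0)) stop("vapor pressure must be non-negative")
  216.7 * e / (T + 273.15)
}

#' Ancestral climate per individual from parental birthplace climates
#'
#' The mean of the available parents' climate values; a single available
#' parent passes through unchanged.
#'
#' @param parentA,parentB data.frames keyed by \code{id} with identical
#'   climate columns; rows missing from one parent (or holding NA values)
#'   fall back to the other parent's values
#' @return data.frame keyed by \code{id} with the averaged climate columns
#' @export
ancestralClimate <- function(parentA, parentB) {
  stopifnot("id" %in% names(parentA), "id" %in% names(parentB))
  vars <- setdiff(intersect(names(parentA), names(parentB)), "id")
  ids <- union(parentA$id, parentB$id)
  a <- parentA[match(ids, parentA$id), vars, drop = FALSE]
  b <- parentB[match(ids, parentB$id), vars, drop = FALSE]
  out <- as.data.frame(lapply(vars, function(v) {
    x <- a[[v]]; y <- b[[v]]
    ifelse(is.na(x), y, ifelse(is.na(y), x, (x + y) / 2))
  }))
  names(out) <- vars
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), out)
}

#' Kinship-corrected phenotype-climate association
#'
#' Fits the linear mixed model \eqn{y = X\beta + \varepsilon} with
#' \eqn{Var(\varepsilon) = \sigma_g^2 K + \sigma_e^2 I} by maximum
#' likelihood (ML, not REML: the likelihood-ratio test compares models with
#' different fixed effects). X contains an intercept, the climate variable,
#' and the covariates. The slope, its standard error and the t statistic
#' come from generalized least squares at the ML variance ratio; the LRT
#' statistic is twice the log-likelihood difference between the full model
#' and the model with the climate column dropped, with the p-value from a
#' 1-df chi-square.
#'
#' With \code{residual = FALSE} the error covariance is taken as
#' \eqn{\sigma^2 K} alone (pure generalized least squares with the kinship
#' as correlation); the default adds an iid residual component, matching
#' standard mixed-model software, because a pure-kinship covariance is
#' typically singular.
#'
#' @param pheno data.frame with \code{id}, the trait and covariate columns
#' @param climate data.frame with \code{id} and the climate column
#' @param trait,climateVar column names
#' @param covariates covariate columns (default age + BMI; sex is excluded
#'   by default because the climate analysis cohort is single-sex)
#' @param K a \linkS4class{KinshipMatrix} whose dimnames match \code{id}
#' @param residual include the iid residual variance component?
#' @return an \linkS4class{AssociationResult}
#' @export
kinshipLmmSlope <- function(pheno, climate, trait, climateVar,
                            covariates = c("age", "bmi"), K,
                            residual = TRUE) {
  stopifnot(is(K, "KinshipMatrix"))
  d <- merge(pheno, climate, by = "id", sort = FALSE)
  unmatched <- setdiff(pheno$id, climate$id)
  if (length(unmatched))
    message(length(unmatched), " individual(s) lack climate values")
  cols <- c(trait, climateVar, covariates)
  missingCols <- setdiff(cols, names(d))
  if (length(missingCols))
    stop("column(s) not found: ", paste(missingCols, collapse = ", "))
  d <- d[complete.cases(d[, cols, drop = FALSE]), , drop = FALSE]
  n <- nrow(d)
  if (n < 3) stop("need at least 3 complete observations")
  if (sd(d[[climateVar]]) == 0) stop("constant climate column")

  Km <- kinship(K)
  idx <- if (!is.null(rownames(Km))) match(d$id, rownames(Km))
         else seq_len(n)
  if (anyNA(idx)) stop("individual(s) absent from the kinship matrix: ",
                       paste(head(d$id[is.na(idx)], 5), collapse = ", "))
  Km <- Km[idx, idx]

  y <- d[[trait]]
  Xfull <- cbind(`(Intercept)` = 1, as.matrix(d[, c(climateVar, covariates),
                                                drop = FALSE]))
  Xred <- Xfull[, colnames(Xfull) != climateVar, drop = FALSE]
  if (qr(Xfull)$rank < ncol(Xfull)) stop("singular design matrix")

  if (residual) {
    rotF <- rotateByKinship(y, Xfull, Km)
    rotR <- list(yr = rotF$yr,
                 Xr = rotF$Xr[, colnames(Xfull) != climateVar, drop = FALSE],
                 lambda = rotF$lambda)
    fitF <- maximizeH2(rotF, reml = FALSE)
    fitR <- maximizeH2(rotR, reml = FALSE)
    gls <- glsAtH2(fitF$h2, rotF, reml = FALSE)
    llF <- fitF$logLik
    llR <- fitR$logLik
    h2 <- fitF$h2
  } else {
    # strict mode: Var(eps) = sigma2 * K, scale profiled out
    rotF <- rotateByKinship(y, Xfull, Km)
    if (any(rotF$lambda < 1e-10 * max(rotF$lambda)))
      stop("kinship matrix is singular; the pure-kinship covariance is ",
           "not usable (set residual = TRUE)")
    pureLL <- function(Xr) {
      sw <- 1 / sqrt(rotF$lambda)
      fit <- .lm.fit(Xr * sw, rotF$yr * sw)
      n <- length(rotF$yr)
      s2 <- sum(fit$residuals^2) / n
      -0.5 * (n * log(2 * pi * s2) + sum(log(rotF$lambda)) + n)
    }
    llF <- pureLL(rotF$Xr)
    llR <- pureLL(rotF$Xr[, colnames(Xfull) != climateVar, drop = FALSE])
    w <- rotF$lambda
    sw <- 1 / sqrt(w)
    Xw <- rotF$Xr * sw; yw <- rotF$yr * sw
    XtX <- crossprod(Xw)
    beta <- solve(XtX, crossprod(Xw, yw))
    s2 <- sum((yw - Xw %*% beta)^2) / length(yw)
    gls <- list(beta = as.numeric(beta), cov = s2 * solve(XtX))
    h2 <- 1
  }

  j <- which(colnames(Xfull) == climateVar)
  slope <- gls$beta[j]
  se <- sqrt(gls$cov[j, j])
  lrt <- max(2 * (llF - llR), 0)
  new("AssociationResult", trait = trait, climateVar = climateVar,
      slope = slope, se = se, tStat = slope / se, lrt = lrt,
      pValue = pchisq(lrt, df = 1, lower.tail = FALSE),
      n = as.integer(n), covariates = as.character(covariates), h2 = h2)
}

#' Leave-one-population-out robustness of a climate slope
#'
#' Refits the kinship LMM after removing each population in turn (the
#' kinship matrix is subset accordingly) and reports the slope with its
#' normal-approximation 95\% confidence interval and whether that interval
#' overlaps zero. The row labelled \code{"none"} is the full-data fit.
#'
#' @inheritParams kinshipLmmSlope
#' @param pheno must additionally carry a \code{population} column
#' @return data.frame: dropped, n, slope, se, lower, upper, overlapsZero
#' @export
leaveOnePopulationOut <- function(pheno, climate, trait, climateVar,
                                  covariates = c("age", "bmi"), K) {
  if (!"population" %in% names(pheno))
    stop("'pheno' must contain a 'population' column")
  pops <- unique(pheno$population)
  fits <- lapply(c("none", pops), function(drop) {
    sub <- if (drop == "none") pheno else
      pheno[pheno$population != drop, , drop = FALSE]
    if (nrow(sub) < 3)
      stop("dropping '", drop, "' leaves fewer than 3 individuals")
    r <- kinshipLmmSlope(sub, climate, trait, climateVar, covariates, K)
    data.frame(dropped = drop, n = r@n, slope = r@slope, se = r@se,
               lower = r@slope - 1.96 * r@se,
               upper = r@slope + 1.96 * r@se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  out$overlapsZero <- out$lower <= 0 & out$upper >= 0
  rownames(out) <- NULL
  out
}
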