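## Kinship construction and single-component REML heritability. The
## eigen-rotated likelihood core here is the one code path for all mixed
## models in the package (REML h2 and the ML climate LMM).

#' Genetic relationship matrix from genotype dosages
#'
#' Standard standardized construction: entry (i, j) is the average over SNPs
#' of \eqn{(x_{si} - 2p_s)(x_{sj} - 2p_s) / (2 p_s (1 - p_s))} with
#' \eqn{p_s} the sample allele frequency. Monomorphic SNPs are skipped;
#' missing dosages are mean-imputed per SNP. The diagonal averages to about
#' 1 (up to \eqn{O(1/\sqrt{M})}).
#'
#' @param genos a \linkS4class{GenotypeMatrix}
#' @return a \linkS4class{KinshipMatrix} with source tag "genotype"
#' @export
grm <- function(genos) {
  stopifnot(is(genos, "GenotypeMatrix"))
  d <- dosage(genos)
  if (ncol(d) < 2) stop("need at least 2 individuals")
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic")
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  if (anyNA(d)) {
    imp <- which(is.na(d), arr.ind = TRUE)
    d[imp] <- 2 * p[imp[, 1]]
  }
  W <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  K <- crossprod(W) / nrow(W)
  KinshipMatrix(K, source = "genotype", nMarkers = nrow(W))
}

#' Genetic relationship matrix from local-ancestry dosages
#'
#' Same standardized averaging applied to local-ancestry dosages, except
#' that each SNP is standardized by its empirical mean and SD rather than
#' the binomial form: ancestry copies on the two haplotypes of one
#' individual are positively correlated (they share the individual's global
#' ancestry), so the Hardy-Weinberg variance would mis-scale the matrix.
#' Zero-variance SNPs are skipped.
#'
#' @param la a \linkS4class{LocalAncestryMatrix}
#' @return a \linkS4class{KinshipMatrix} with source tag "local-ancestry"
#' @export
ancestryGrm <- function(la) {
  stopifnot(is(la, "LocalAncestryMatrix"))
  A <- ancestryDosage(la)
  if (ncol(A) < 2) stop("need at least 2 individuals")
  sds <- apply(A, 1, sd)
  keep <- sds > 0
  if (!any(keep))
    stop("degenerate local ancestry: no SNP varies across individuals")
  W <- (A[keep, , drop = FALSE] - rowMeans(A[keep, , drop = FALSE])) /
    sds[keep]
  K <- crossprod(W) / nrow(W)
  KinshipMatrix(K, source = "local-ancestry", nMarkers = sum(keep))
}

#' Leading principal components of a kinship matrix
#'
#' Eigenvectors scaled by the root eigenvalue, with a deterministic sign
#' convention (the largest-magnitude loading of each component is made
#' positive) so repeated runs are identical.
#'
#' @param K a \linkS4class{KinshipMatrix}
#' @param k number of components (k < n)
#' @return n x k matrix of PC scores (rownames = individual ids)
#' @export
topPCs <- function(K, k = 4) {
  stopifnot(is(K, "KinshipMatrix"))
  M <- kinship(K)
  if (k >= nrow(M)) stop("k must be smaller than the number of individuals")
  e <- eigen(M, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  val <- pmax(e$values[seq_len(k)], 0)
  for (j in seq_len(k)) {
    lead <- which.max(abs(vec[, j]))
    if (vec[lead, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(val), "*")
  dimnames(scores) <- list(rownames(M), paste0("PC", seq_len(k)))
  scores
}

## ---------------------------------------------------------------------------
## Eigen-rotated likelihood core
## ---------------------------------------------------------------------------

## Rotate (y, X) into the kinship eigenbasis. Negative eigenvalues (from
## numerically non-PSD input) are clipped at zero with a warning.
rotateByKinship <- function(y, X, K) {
  e <- eigen(K, symmetric = TRUE)
  lambda <- e$values
  if (any(lambda < -1e-8 * max(abs(lambda))))
    warning("kinship matrix not PSD; clipping negative eigenvalues at 0")
  # snap numerically-zero eigenvalues (e.g. the centred-GRM constant
  # direction) to exact zero: the profiled likelihood is then -Inf at
  # h2 = 1 and the optimizer stays off the singular boundary
  lambda[lambda < 1e-10 * max(abs(lambda), 1)] <- 0
  list(yr = as.numeric(crossprod(e$vectors, y)),
       Xr = crossprod(e$vectors, X), lambda = lambda)
}

## Profiled log-likelihood at heritability h2 (variance = sigma2 *
## (h2 * Lambda + (1 - h2) I) in the rotated basis). REML profiles out
## sigma2 and the fixed effects; ML profiles out sigma2 at the GLS beta.
profileLogLik <- function(h2, rot, reml = TRUE) {
  w <- h2 * rot$lambda + (1 - h2)
  if (any(w <= 0)) return(-Inf)
  sw <- 1 / sqrt(w)
  Xw <- rot$Xr * sw
  yw <- rot$yr * sw
  fit <- .lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  n <- length(yw)
  p <- fit$rank
  if (reml) {
    s2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
              determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  } else {
    s2 <- rss / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
  }
}

## maximize the profiled likelihood over h2 in [0, 1]
maximizeH2 <- function(rot, reml = TRUE, tol = 1e-6) {
  f <- function(h) profileLogLik(h, rot, reml)
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, f(0)), c(1, f(1)))
  best <- cand[which.max(cand[, 2]), ]
  list(h2 = best[1], logLik = as.numeric(best[2]))
}

## GLS fixed effects, their covariance and the scale at a given h2
glsAtH2 <- function(h2, rot, reml = TRUE) {
  w <- h2 * rot$lambda + (1 - h2)
  sw <- 1 / sqrt(w)
  Xw <- rot$Xr * sw
  yw <- rot$yr * sw
  XtX <- crossprod(Xw)
  beta <- solve(XtX, crossprod(Xw, yw))
  rss <- sum((yw - Xw %*% beta)^2)
  n <- length(yw)
  s2 <- if (reml) rss / (n - ncol(Xw)) else rss / n
  list(beta = as.numeric(beta), cov = s2 * solve(XtX), sigma2 = s2)
}

#' Single-component REML heritability
#'
#' Fits \eqn{y = X\beta + g + e} with \eqn{g \sim N(0, K\sigma_g^2)} and
#' \eqn{e \sim N(0, I\sigma_e^2)} by REML, maximizing the eigen-rotated
#' profile likelihood over \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)}
#' with derivative-free one-dimensional optimization (tolerance 1e-6).
#' The standard error comes from the observed information (numerical
#' curvature of the profile REML log-likelihood); estimates on the boundary
#' (0 or 1) are flagged.
#'
#' Rows with missing response or covariates are dropped listwise (with a
#' message) and the kinship matrix is subset accordingly.
#'
#' @param y numeric response vector (names or order matching \code{K})
#' @param X covariate design: a data.frame (expanded with an intercept via
#'   \code{model.matrix(~ .)}) or a numeric model matrix; \code{NULL} fits
#'   an intercept only
#' @param K a \linkS4class{KinshipMatrix}
#' @return a \linkS4class{HeritabilityEstimate}; the \code{kind} tag is
#'   \code{"h_g2"} for a genotype kinship and \code{"h_y2"} (the estimator
#'   of the between-population heritability c) for a local-ancestry kinship
#' @export
remlH2 <- function(y, X = NULL, K) {
  stopifnot(is(K, "KinshipMatrix"))
  n <- length(y)
  if (nrow(kinship(K)) != n)
    stop("length(y) must match the kinship dimension")
  covNames <- if (is.data.frame(X)) names(X) else
    if (!is.null(X)) colnames(X) else character(0)
  Xm <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
        else if (is.data.frame(X)) NULL   # built after NA handling
        else as.matrix(X)

  keep <- if (is.data.frame(X)) complete.cases(y, X) else
    complete.cases(y, if (is.null(X)) rep(TRUE, n) else Xm)
  if (any(!keep))
    message(sum(!keep), " row(s) dropped for missing values")
  y <- y[keep]
  if (is.data.frame(X)) Xm <- model.matrix(~ ., X[keep, , drop = FALSE])
  else Xm <- Xm[keep, , drop = FALSE]
  if (!any(apply(Xm, 2, function(col) all(col == col[1]))))
    Xm <- cbind(`(Intercept)` = 1, Xm)
  Ksub <- kinship(K)[keep, keep]
  if (length(y) <= qr(Xm)$rank) stop("n must exceed rank(X)")

  rot <- rotateByKinship(y, Xm, Ksub)
  fit <- maximizeH2(rot, reml = TRUE)
  h2 <- fit$h2
  gls <- glsAtH2(h2, rot, reml = TRUE)

  # observed information from the profile curvature
  eps <- 1e-3
  hlo <- max(h2 - eps, 0); hhi <- min(h2 + eps, 1)
  d2 <- (profileLogLik(hlo, rot) - 2 * profileLogLik(h2, rot) +
           profileLogLik(hhi, rot)) / ((hhi - h2) * (h2 - hlo) +
                                         .Machine$double.eps)
  se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  boundary <- h2 < 1e-4 || h2 > 1 - 1e-4
  kind <- switch(K@source, genotype = "h_g2", `local-ancestry` = "h_y2",
                 "h2")
  new("HeritabilityEstimate", h2 = h2, se = se,
      sigmaG2 = h2 * gls$sigma2, sigmaE2 = (1 - h2) * gls$sigma2,
      logLik = fit$logLik, kind = kind, n = length(y),
      covariates = if (length(covNames)) covNames else "(Intercept)",
      boundary = boundary)
}
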