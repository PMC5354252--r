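## Geometric morphometrics of the 7-landmark nose configuration, mesh region
## areas, the melanin-index transform, and observer-reliability statistics.

requiredLandmarks <- c("n", "prn", "sn", "al_l", "al_r", "ac_l", "ac_r")

asConfigArray <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3) return(configs)
  if (is.list(configs)) {
    p <- nrow(configs[[1]])
    arr <- array(NA_real_, c(p, 3, length(configs)),
                 dimnames = list(rownames(configs[[1]]), NULL,
                                 names(configs)))
    for (i in seq_along(configs)) arr[, , i] <- as.matrix(configs[[i]])
    return(arr)
  }
  stop("configs must be a p x 3 x N array or a list of p x 3 matrices")
}

## optimal rotation of X onto Y (both centred): Kabsch via SVD, with
## reflection guard so only proper rotations are returned
kabschRotate <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  X %*% (s$u %*% D %*% t(s$v))
}

#' Generalized Procrustes superimposition
#'
#' Removes translation and rotation from a set of homologous landmark (or
#' vertex) configurations by iterative superimposition onto the evolving
#' consensus. Scale is \emph{not} removed by default: the downstream traits
#' are absolute distances in mm and areas in mm2, so superimposition is used
#' only to standardize position and orientation (set \code{scale = TRUE}
#' for classical full GPA).
#'
#' @param configs p x 3 x N array or list of N p x 3 matrices with
#'   homologous row ordering
#' @param scale remove centroid size as well? (default \code{FALSE})
#' @param tol convergence tolerance on the consensus root-mean-square change
#' @param maxIter iteration cap
#' @return list with \code{aligned} (p x 3 x N array), \code{consensus}
#'   (p x 3), and \code{iterations}
#' @export
procrustesAlign <- function(configs, scale = FALSE, tol = 1e-10,
                            maxIter = 100) {
  arr <- asConfigArray(configs)
  N <- dim(arr)[3]
  if (N < 2) stop("need at least 2 configurations")
  for (i in seq_len(N)) {
    X <- arr[, , i]
    X <- sweep(X, 2, colMeans(X))
    cs <- sqrt(sum(X^2))
    if (cs < 1e-12)
      stop("configuration ", i, " is degenerate (all points coincident)")
    if (scale) X <- X / cs
    arr[, , i] <- X
  }
  consensus <- apply(arr, c(1, 2), mean)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(N)) arr[, , i] <- kabschRotate(arr[, , i], consensus)
    newCons <- apply(arr, c(1, 2), mean)
    delta <- sqrt(mean((newCons - consensus)^2))
    consensus <- newCons
    if (delta < tol || iter >= maxIter) break
  }
  list(aligned = arr, consensus = consensus, iterations = iter)
}

#' Reflect a configuration and relabel paired landmarks
#'
#' Mirror image about the midsagittal (x = 0) plane: x coordinates are
#' negated and left/right landmark labels swapped according to
#' \code{pairing}.
#'
#' @param config p x 3 matrix with landmark rownames
#' @param pairing named character vector mapping each paired landmark to its
#'   contralateral partner (must be an involution); unlisted landmarks are
#'   treated as midline
#' @export
reflectConfig <- function(config,
                          pairing = c(al_l = "al_r", al_r = "al_l",
                                      ac_l = "ac_r", ac_r = "ac_l")) {
  checkInvolution(pairing)
  out <- config
  out[, 1] <- -out[, 1]
  nm <- rownames(out)
  swapped <- ifelse(nm %in% names(pairing), pairing[nm], nm)
  rownames(out) <- swapped
  out[rownames(config), , drop = FALSE]
}

checkInvolution <- function(pairing) {
  back <- pairing[pairing]
  if (!all(back == names(pairing)))
    stop("pairing map is not an involution")
  invisible(TRUE)
}

#' Symmetrize a configuration against its relabeled reflection
#'
#' Pointwise mean of the original configuration and its (Procrustes-aligned,
#' relabeled) mirror image. The output is bilaterally symmetric: midline
#' landmarks land on the symmetry plane and paired landmarks split any
#' left/right difference.
#'
#' @param original,reflected p x 3 matrices with identical landmark
#'   rownames (the reflection already relabeled, e.g. via
#'   [reflectConfig()] followed by alignment)
#' @param pairing the left/right label map; checked to be an involution
#' @return p x 3 symmetric configuration
#' @export
symmetrizeConfig <- function(original, reflected,
                             pairing = c(al_l = "al_r", al_r = "al_l",
                                         ac_l = "ac_r", ac_r = "ac_l")) {
  checkInvolution(pairing)
  if (!identical(rownames(original), rownames(reflected)))
    reflected <- reflected[rownames(original), , drop = FALSE]
  (original + reflected) / 2
}

#' Linear distances from the seven nose landmarks
#'
#' Euclidean distances in mm: nares width |al_l - al_r|, alar base width
#' |ac_l - ac_r|, nasal height |n - sn|, nasal ridge length |n - prn|,
#' nasal tip protrusion |sn - prn|.
#'
#' @param lm 7 x 3 numeric matrix with rownames among
#'   \code{c("n","prn","sn","al_l","al_r","ac_l","ac_r")}
#' @return named numeric vector of the five distances
#' @examples
#' lm <- noseTemplate <- matrix(0, 7, 3,
#'   dimnames = list(c("n","prn","sn","al_l","al_r","ac_l","ac_r"), NULL))
#' lm["al_r", ] <- c(3, 4, 0)
#' landmarkDistances(lm)[["nares_width"]]  # 5
#' @export
landmarkDistances <- function(lm) {
  lm <- as.matrix(lm)
  missing <- setdiff(requiredLandmarks, rownames(lm))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  if (!all(is.finite(lm[requiredLandmarks, ])))
    stop("non-finite landmark coordinates")
  d <- function(a, b) sqrt(sum((lm[a, ] - lm[b, ])^2))
  c(nares_width = d("al_l", "al_r"),
    alar_base_width = d("ac_l", "ac_r"),
    nasal_height = d("n", "sn"),
    nasal_ridge_length = d("n", "prn"),
    nasal_tip_protrusion = d("sn", "prn"))
}

#' Per-placement distances from a long landmark table
#'
#' @param lmTable data.frame with columns id, observer, replicate, landmark,
#'   x, y, z; ids lacking any of the seven landmarks in a placement are
#'   excluded with a message
#' @return data.frame with one row per (id, observer, replicate) and the
#'   five distance columns
#' @export
replicateDistances <- function(lmTable) {
  need <- c("id", "observer", "replicate", "landmark", "x", "y", "z")
  missing <- setdiff(need, names(lmTable))
  if (length(missing))
    stop("landmark table lacks column(s): ", paste(missing, collapse = ", "))
  key <- interaction(lmTable$id, lmTable$observer, lmTable$replicate,
                     drop = TRUE)
  pieces <- split(lmTable, key)
  rows <- lapply(pieces, function(p) {
    if (!all(requiredLandmarks %in% p$landmark)) return(NULL)
    m <- as.matrix(p[, c("x", "y", "z")])
    rownames(m) <- p$landmark
    cbind(data.frame(id = p$id[1], observer = p$observer[1],
                     replicate = p$replicate[1], stringsAsFactors = FALSE),
          as.data.frame(as.list(landmarkDistances(m))))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    message(dropped, " placement(s) excluded for missing landmarks")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no complete landmark placements")
  rownames(out) <- NULL
  out
}

#' Average replicate distances into per-individual traits
#'
#' Averaging order follows the measurement protocol: mean across a single
#' observer's replicates first, then mean across observers.
#'
#' @param repDist output of [replicateDistances()]
#' @return data.frame keyed by id with the five distance columns
#' @export
averageReplicates <- function(repDist) {
  traits <- setdiff(names(repDist), c("id", "observer", "replicate"))
  perObs <- stats::aggregate(repDist[traits],
                             by = repDist[c("id", "observer")], FUN = mean)
  out <- stats::aggregate(perObs[traits], by = perObs["id"], FUN = mean)
  out[order(out$id), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Mesh areas
## ---------------------------------------------------------------------------

#' Surface area of a mesh region
#'
#' Sums triangle areas (half cross-product norm) over the faces whose three
#' vertices all belong to the region mask. Rigid motion of the mesh leaves
#' the result unchanged.
#'
#' @param mesh list with \code{vertices} (V x 3 numeric) and \code{faces}
#'   (F x 3 integer, 1-based vertex indices)
#' @param region integer vector of 1-based vertex indices defining the
#'   region (default: all vertices)
#' @return area in the square of the vertex coordinate unit (mm2)
#' @export
regionArea <- function(mesh, region = seq_len(nrow(mesh$vertices))) {
  V <- as.matrix(mesh$vertices)
  Fc <- as.matrix(mesh$faces)
  if (ncol(V) != 3 || ncol(Fc) != 3) stop("mesh must be triangulated 3D")
  if (max(Fc) > nrow(V) || min(Fc) < 1) stop("face indices out of range")
  if (!length(region)) stop("empty region")
  inRegion <- matrix(Fc %in% region, nrow(Fc))
  keep <- rowSums(inRegion) == 3L
  if (!any(keep)) stop("region contains no complete triangle")
  tri <- Fc[keep, , drop = FALSE]
  e1 <- V[tri[, 2], , drop = FALSE] - V[tri[, 1], , drop = FALSE]
  e2 <- V[tri[, 3], , drop = FALSE] - V[tri[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cx^2))) / 2
}

#' Nose surface-area traits from a mesh with region masks
#'
#' @param mesh triangulated mesh (see [regionArea()])
#' @param noseRegion vertex mask of the whole external nose
#' @param nostrilLeft,nostrilRight vertex masks of the two nostril regions;
#'   the nostril-area trait is the mean of the two
#' @return named vector: external_surface_area, nostril_area (mm2)
#' @export
meshAreas <- function(mesh, noseRegion, nostrilLeft, nostrilRight) {
  c(external_surface_area = regionArea(mesh, noseRegion),
    nostril_area = (regionArea(mesh, nostrilLeft) +
                      regionArea(mesh, nostrilRight)) / 2)
}

## ---------------------------------------------------------------------------
## Melanin index
## ---------------------------------------------------------------------------

#' Melanin index from skin reflectance at 650 nm
#'
#' \eqn{MI = 100 \log_{10}(1 / \mathrm{reflectance})} with reflectance as a
#' fraction in (0, 1]. Values above 1 are interpreted as percent reflectance
#' and divided by 100 (with a warning): observed melanin indices of roughly
#' 26-60 are only consistent with the fractional form.
#'
#' @param reflectance numeric vector of reflectance fractions (or percents)
#' @return melanin index, same length
#' @examples
#' melaninIndex(0.5)   # 30.103
#' @export
melaninIndex <- function(reflectance) {
  if (any(!is.finite(reflectance)) || any(reflectance <= 0))
    stop("reflectance must be positive and finite")
  if (any(reflectance > 1)) {
    if (any(reflectance > 100))
      stop("reflectance above 100 percent")
    warning("reflectance > 1 supplied; interpreting as percent")
    reflectance <- reflectance / 100
  }
  100 * log10(1 / reflectance)
}

#' Mean melanin index over replicate readings
#'
#' Per-individual melanin index is the mean over the replicate reflectance
#' readings (conventionally three from each inner arm).
#'
#' @param readings numeric matrix, one row per individual, columns =
#'   replicate reflectance readings
#' @export
meanMelaninIndex <- function(readings) {
  m <- as.matrix(readings)
  rowMeans(matrix(melaninIndex(as.numeric(m)), nrow(m)))
}

#' Inverse melanin index
#'
#' \code{1/MI}; the inverse is closer to normal and is the scale used for
#' statistical testing of pigmentation associations.
#'
#' @param mi melanin index values (> 0)
#' @export
inverseMelaninIndex <- function(mi) {
  if (any(mi <= 0)) stop("melanin index must be positive for the inverse")
  1 / mi
}

## ---------------------------------------------------------------------------
## Observer reliability
## ---------------------------------------------------------------------------

#' Intraclass correlation and intra-observer error for a replicated trait
#'
#' Fits the two-way model with observer as a fixed effect and subject as a
#' random effect (via \code{nlme::lme}) and returns
#' \eqn{ICC = \sigma^2_{subject} / (\sigma^2_{subject} + \sigma^2_{error})},
#' together with the 2.5\% / 97.5\% quantiles of the per-subject
#' within-observer replicate SDs (intra-observer error). When the replicate
#' noise is numerically zero the mixed model is degenerate and the ICC is 1
#' by definition.
#'
#' @param measurements data.frame with columns \code{subject},
#'   \code{observer}, \code{value} (replicates as repeated rows)
#' @return list: \code{icc}, \code{varSubject}, \code{varError},
#'   \code{intraObserver} (data.frame observer / lower / upper)
#' @export
iccReliability <- function(measurements) {
  need <- c("subject", "observer", "value")
  if (!all(need %in% names(measurements)))
    stop("measurements needs columns subject, observer, value")
  d <- measurements
  d$subject <- factor(d$subject)
  d$observer <- factor(d$observer)
  if (nlevels(d$subject) < 2)
    stop("ICC undefined for a single subject")
  if (nlevels(d$observer) < 2 && !any(table(d$subject, d$observer) >= 2))
    stop("need >= 2 observers or >= 2 replicates per subject")

  # intra-observer error: SD across one observer's replicates of a subject
  sds <- stats::aggregate(value ~ subject + observer, data = d, FUN = sd)
  intra <- do.call(rbind, lapply(split(sds, sds$observer), function(s) {
    data.frame(observer = s$observer[1],
               lower = quantile(s$value, 0.025, na.rm = TRUE),
               upper = quantile(s$value, 0.975, na.rm = TRUE))
  }))
  rownames(intra) <- NULL

  cellResid <- d$value - ave(d$value, d$subject, d$observer)
  fit <- NULL
  if (var(d$value - ave(d$value, d$subject)) > 1e-12 &&
      sd(cellResid) > 1e-8 * max(1, sd(d$value)))
    fit <- tryCatch(
      nlme::lme(value ~ observer, random = ~ 1 | subject, data = d),
      error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate (zero replicate noise): perfect reliability
    varS <- var(tapply(d$value, d$subject, mean))
    out <- list(icc = 1, varSubject = varS, varError = 0,
                intraObserver = intra)
    return(out)
  }
  vc <- as.numeric(nlme::VarCorr(fit)[, "Variance"])
  varSubject <- vc[1]
  varError <- vc[2]
  list(icc = varSubject / (varSubject + varError),
       varSubject = varSubject, varError = varError,
       intraObserver = intra)
}
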