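## Synthetic-data generators with known ground truth. Every downstream stage
## (Qst, Fst, divergence test, heritability, climate LMM, morphometrics) has
## a parameter-recovery test built on these.

#' Simulation configuration for discrete drifted populations
#'
#' Defaults mirror the four-continental-population study design: population
#' sizes 40/236/127/73, a LD-pruned-scale SNP panel, and a target
#' multi-locus Fst of 0.12.
#'
#' @param nPops number of populations
#' @param nPerPop individuals per population (recycled to length
#'   \code{nPops})
#' @param nSnps number of independent biallelic SNPs
#' @param targetFst Balding-Nichols drift parameter F in [0, 1); interpreted
#'   as the Weir-Cockerham theta the panel should realize
#' @param mafRange interval in (0, 0.5] for the ancestral allele frequency
#' @param sigma2gb,sigma2gw between-/within-population additive genetic
#'   variances (trait units squared)
#' @param h2 within-population heritability in [0, 1]
#' @param c between-population heritability in [0, 1]
#' @param covariateEffects named numeric vector of slopes for
#'   \code{sex} (added to males), \code{age} (per year) and \code{bmi}
#'   (per unit)
#' @param betweenMode \code{"exact"} scales the realized between-population
#'   effects to exactly \code{sigma2gb} (parameter-recovery semantics);
#'   \code{"drift"} draws them \code{N(0, sigma2gb)}, emulating the
#'   evolutionary sampling of a neutral trait (null-calibration semantics)
#' @param seed integer seed; all generator randomness flows from it
#' @return a validated \linkS4class{SimConfig}
#' @export
simConfig <- function(nPops = 4, nPerPop = c(40, 236, 127, 73),
                      nSnps = 20000, targetFst = 0.12,
                      mafRange = c(0.05, 0.5),
                      sigma2gb = 1, sigma2gw = 1, h2 = 0.5, c = 0.5,
                      covariateEffects = c(sex = 4, age = 0.05, bmi = 0.1),
                      betweenMode = "exact", seed = 1) {
  nPerPop <- rep_len(as.integer(nPerPop), nPops)
  new("SimConfig", nPops = as.integer(nPops), nPerPop = nPerPop,
      nSnps = as.integer(nSnps), targetFst = targetFst,
      mafRange = as.numeric(mafRange), sigma2gb = sigma2gb,
      sigma2gw = sigma2gw, h2 = h2, c = c,
      covariateEffects = covariateEffects, betweenMode = betweenMode,
      seed = as.integer(seed))
}

#' Simulation configuration for a two-way admixed cohort
#'
#' Defaults mirror the admixed West African / European cohort used for the
#' between-population heritability: 409 individuals, mean ancestry about
#' 0.6, ancestry tracts of geometric length, parental differentiation 0.15.
#'
#' @param nInd cohort size
#' @param nSnps number of SNPs carrying local ancestry
#' @param ancestryMean mean global ancestry from the designated parental
#'   population, in (0, 1)
#' @param tractMeanSnps mean ancestry tract length in SNPs (geometric)
#' @param hy2Target proportion of trait variance explained by local
#'   ancestry (the generator's ground-truth c)
#' @param parentalFst drift between the two parental populations
#' @param seed integer seed
#' @return a validated \linkS4class{AdmixSimConfig}
#' @export
admixSimConfig <- function(nInd = 409, nSnps = 2000, ancestryMean = 0.6,
                           tractMeanSnps = 20, hy2Target = 0.22,
                           parentalFst = 0.15, seed = 1) {
  new("AdmixSimConfig", nInd = as.integer(nInd), nSnps = as.integer(nSnps),
      ancestryMean = ancestryMean, tractMeanSnps = as.numeric(tractMeanSnps),
      hy2Target = hy2Target, parentalFst = parentalFst,
      seed = as.integer(seed))
}

## exact second-moment scaling: returns x recentred/rescaled so that
## mean(x) = 0 and var(x) = v (sample variance, n-1 denominator)
scaleToVar <- function(x, v) {
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0 || v == 0) return(x * 0)
  x * sqrt(v) / s
}

## exact scaling of per-population effects against the ANOVA estimand:
## the moment estimator sigma2pb = (MSB - MSW)/n0 is consistent for
## sum(n_i (mu_i - mu_w)^2) / (n0 (a - 1)), which reduces to the plain
## sample variance when groups are balanced. Scaling to this weighted form
## keeps the realized between-population variance on target for unbalanced
## cohorts too.
scalePopEffects <- function(z, v, ni) {
  n <- sum(ni)
  a <- length(ni)
  n0 <- (n - sum(ni^2) / n) / (a - 1)
  z <- z - sum(ni * z) / n
  s <- sum(ni * z^2) / (n0 * (a - 1))
  if (s == 0 || v == 0) return(z * 0)
  z * sqrt(v / s)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' Per SNP an ancestral frequency p is drawn uniformly from
#' \code{mafRange}; each population's frequency is drawn from
#' \code{Beta(p(1-F)/F, (1-p)(1-F)/F)} with F = \code{targetFst}
#' (shared frequencies when F = 0), and diploid dosages are sampled under
#' Hardy-Weinberg within population.
#'
#' @param cfg a \linkS4class{SimConfig}
#' @return a \linkS4class{GenotypeMatrix} with population labels attached
#' @seealso [wcTheta()] recovers \code{targetFst} as the multi-locus theta
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  K <- cfg@nPops
  S <- cfg@nSnps
  F <- cfg@targetFst
  p <- runif(S, cfg@mafRange[1], cfg@mafRange[2])
  popFreq <- if (F == 0) {
    matrix(p, S, K)
  } else {
    vapply(seq_len(K), function(k)
      rbeta(S, p * (1 - F) / F, (1 - p) * (1 - F) / F),
      numeric(S))
  }
  dos <- matrix(NA_real_, S, sum(cfg@nPerPop))
  col0 <- 0L
  for (k in seq_len(K)) {
    nk <- cfg@nPerPop[k]
    dos[, col0 + seq_len(nk)] <- rbinom(S * nk, 2L, rep(popFreq[, k], nk))
    col0 <- col0 + nk
  }
  GenotypeMatrix(dos, population = rep(paste0("pop", seq_len(K)),
                                       cfg@nPerPop))
}

#' Simulate a polygenic trait over simulated populations
#'
#' The trait is the sum of a population genetic mean (between-population
#' additive variance \code{sigma2gb}), an individual additive deviation
#' built from the standardized genotypes and centred within population
#' (within-population additive variance \code{sigma2gw}), environmental
#' noise scaled so the within-population heritability equals \code{h2} and
#' the between-population heritability equals \code{c}, plus sex/age/BMI
#' covariate effects.
#'
#' With \code{h2 = 0} the additive deviation is omitted and the
#' within-population variance is purely environmental (of magnitude
#' \code{sigma2gw}); \code{c > 0} with \code{sigma2gb = 0} is rejected at
#' configuration time.
#'
#' @param genos a \linkS4class{GenotypeMatrix} from [simulateGenotypes()]
#' @param cfg the same \linkS4class{SimConfig}
#' @return a phenotype data.frame (columns \code{id}, \code{population},
#'   \code{sex}, \code{age}, \code{bmi}, \code{trait}) with a
#'   \code{"truth"} attribute recording the generating components and the
#'   implied true Qst
#' @export
simulatePhenotype <- function(genos, cfg) {
  stopifnot(is(genos, "GenotypeMatrix"), is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed + 1000L)   # own stream; reproducible given cfg
  pop <- factor(population(genos))
  K <- nlevels(pop)
  n <- length(pop)

  # population genetic means
  ni <- as.integer(table(pop))
  gb <- if (cfg@sigma2gb > 0) {
    z <- rnorm(K)
    if (cfg@betweenMode == "exact") scalePopEffects(z, cfg@sigma2gb, ni)
    else z * sqrt(cfg@sigma2gb)
  } else numeric(K)

  # within-population additive deviations from the genotypes
  gw <- numeric(n)
  if (cfg@h2 > 0 && cfg@sigma2gw > 0) {
    d <- dosage(genos)
    pHat <- rowMeans(d) / 2
    poly <- pHat > 0 & pHat < 1
    W <- (d[poly, , drop = FALSE] - 2 * pHat[poly]) /
      sqrt(2 * pHat[poly] * (1 - pHat[poly]))
    u <- rnorm(nrow(W))
    gw <- as.numeric(crossprod(W, u)) / sqrt(nrow(W))
    gw <- gw - ave(gw, pop)                       # pure within-population
    gw <- gw * sqrt(cfg@sigma2gw) /
      sqrt(sum(tapply(gw, pop, function(x) sum((x - mean(x))^2))) / (n - K))
  }

  # environmental noise: within, scaled for h2 (orthogonalized against the
  # additive deviations so the realized within-population variance is
  # exactly sigma2gw / h2) ...
  sigmaEw2 <- if (cfg@h2 > 0) cfg@sigma2gw * (1 - cfg@h2) / cfg@h2
              else cfg@sigma2gw
  ew <- rnorm(n, 0, 1)
  ew <- ew - ave(ew, pop)
  if (sd(gw) > 0) ew <- ew - gw * sum(ew * gw) / sum(gw^2)
  pooled <- sum(tapply(ew, pop, function(x) sum((x - mean(x))^2))) / (n - K)
  ew <- if (sigmaEw2 > 0) ew * sqrt(sigmaEw2 / pooled) else ew * 0

  # ... and between, scaled for c. In "exact" mode the environmental
  # population effects are orthogonalized against the genetic ones (their
  # chance covariance over a handful of populations would otherwise
  # dominate the realized between-population variance).
  eb <- numeric(K)
  if (cfg@c > 0 && cfg@c < 1) {
    sigmaEb2 <- cfg@sigma2gb * (1 - cfg@c) / cfg@c
    z <- rnorm(K)
    if (cfg@betweenMode == "exact") {
      if (K >= 3 && sd(gb) > 0) {
        z <- resid(lm(z ~ gb, weights = ni))
        eb <- scalePopEffects(z, sigmaEb2, ni)
      } else if (sd(gb) > 0) {
        eb <- gb * sqrt(sigmaEb2 / cfg@sigma2gb)  # K = 2: confounded
      } else {
        eb <- scalePopEffects(z, sigmaEb2, ni)
      }
    } else {
      eb <- z * sqrt(sigmaEb2)
    }
  }

  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- runif(n, 18, 40)
  bmi <- rnorm(n, 24, 3)
  eff <- cfg@covariateEffects
  covPart <- eff[["sex"]] * (sex == "male") + eff[["age"]] * age +
    eff[["bmi"]] * bmi

  trait <- gb[as.integer(pop)] + eb[as.integer(pop)] + gw + ew + covPart
  out <- data.frame(id = paste0("ind", seq_len(n)),
                    population = as.character(pop),
                    sex = sex, age = age, bmi = bmi, trait = trait,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(
    sigma2gb = if (cfg@sigma2gb > 0) var(gb) else 0,
    sigma2gw = cfg@sigma2gw, h2 = cfg@h2, c = cfg@c,
    trueQst = if (cfg@sigma2gb + cfg@sigma2gw > 0)
      cfg@sigma2gb / (cfg@sigma2gb + 2 * cfg@sigma2gw) else 0)
  out
}

## one haplotype's ancestry chain: 2-state Markov process with switch rate
## lambda and stationary probability q of carrying the designated ancestry
simulateHaplotypeTracts <- function(nSnps, q, lambda) {
  switches <- c(TRUE, runif(nSnps - 1) < lambda)
  block <- cumsum(switches)
  draws <- rbinom(max(block), 1L, q)
  draws[block]
}

#' Simulate a two-way admixed cohort with local-ancestry tracts
#'
#' Global ancestry per individual is Beta-distributed around
#' \code{ancestryMean}; each of the two haplotypes is an ancestry mosaic
#' with geometric tract lengths (mean \code{tractMeanSnps}) whose stationary
#' frequency is the individual's global ancestry. Genotypes are drawn from
#' the ancestral-population allele frequency underlying each haplotype's
#' local ancestry (parental populations drifted apart by
#' \code{parentalFst}). The trait is built from standardized local-ancestry
#' dosages so that the variance explained by local ancestry equals
#' \code{hy2Target}.
#'
#' @param cfg an \linkS4class{AdmixSimConfig}
#' @return list with elements \code{la} (\linkS4class{LocalAncestryMatrix}),
#'   \code{genotypes} (\linkS4class{GenotypeMatrix}), and \code{pheno}
#'   (data.frame with id, population, sex, age, bmi, globalAncestry, trait)
#' @export
simulateAdmixedCohort <- function(cfg) {
  stopifnot(is(cfg, "AdmixSimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nInd
  S <- cfg@nSnps
  m <- cfg@ancestryMean
  conc <- 8                                   # Beta concentration: broad,
  q <- rbeta(n, m * conc, (1 - m) * conc)     # Cape-Verde-like spread
  q <- pmin(pmax(q, 0.02), 0.98)
  lambda <- 1 / cfg@tractMeanSnps

  hap1 <- vapply(q, function(qi) simulateHaplotypeTracts(S, qi, lambda),
                 integer(S))
  hap2 <- vapply(q, function(qi) simulateHaplotypeTracts(S, qi, lambda),
                 integer(S))
  la <- hap1 + hap2                           # S x n, dosages in 0..2

  # parental allele frequencies under Balding-Nichols drift
  F <- cfg@parentalFst
  p0 <- runif(S, 0.05, 0.95)
  pA <- rbeta(S, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  pB <- rbeta(S, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
  freq1 <- ifelse(hap1 == 1L, pA, pB)
  freq2 <- ifelse(hap2 == 1L, pA, pB)
  geno <- matrix(rbinom(S * n, 1L, freq1) + rbinom(S * n, 1L, freq2), S, n)

  # ancestry-linked polygenic effects
  sdL <- apply(la, 1, sd)
  inf <- sdL > 0
  W <- (la[inf, , drop = FALSE] - rowMeans(la[inf, , drop = FALSE])) /
    sdL[inf]
  u <- rnorm(nrow(W))
  g <- as.numeric(crossprod(W, u)) / sqrt(nrow(W))
  trait <- if (cfg@hy2Target > 0) {
    scaleToVar(g, cfg@hy2Target) +
      scaleToVar(rnorm(n), 1 - cfg@hy2Target)
  } else {
    scaleToVar(rnorm(n), 1)
  }

  ids <- paste0("adm", seq_len(n))
  laObj <- LocalAncestryMatrix(la, individualIds = ids)
  genoObj <- GenotypeMatrix(geno, population = rep("admixed", n),
                            individualIds = ids)
  pheno <- data.frame(id = ids, population = "admixed",
                      sex = sample(c("male", "female"), n, replace = TRUE),
                      age = runif(n, 18, 40), bmi = rnorm(n, 24, 3),
                      globalAncestry = colMeans(la) / 2, trait = trait,
                      stringsAsFactors = FALSE)
  list(la = laObj, genotypes = genoObj, pheno = pheno)
}

## anatomically plausible 7-landmark template, coordinates in mm
## (x lateral, y vertical, z anterior)
noseTemplate <- function() {
  rbind(n     = c(0, 52, 0),
        prn   = c(0, 10, 18),
        sn    = c(0, 0, 8),
        al_l  = c(-17, 8, 10),
        al_r  = c(17, 8, 10),
        ac_l  = c(-18, 4, 6),
        ac_r  = c(18, 4, 6))
}

#' Simulate replicated 3D landmark configurations
#'
#' Generates the seven nose landmarks (n, prn, sn, al_l, al_r, ac_l, ac_r)
#' for \code{nInd} subjects with between-subject anatomical variation
#' (\code{subjectSd} per coordinate), optional per-population landmark
#' shifts, and independent observer placement noise (\code{noiseSd} per
#' coordinate) for each observer x replicate placement. At the distance
#' level a placement noise of \code{subjectSd/3} yields a 9:1
#' subject-to-error variance ratio, i.e. ICC about 0.9.
#'
#' @param nInd number of subjects
#' @param popOffsets optional named list (population -> named list of
#'   landmark -> length-3 shift in mm); subjects are split evenly across the
#'   named populations
#' @param noiseSd observer placement noise SD per coordinate (mm)
#' @param nObservers,nReps placements per subject
#' @param subjectSd between-subject anatomical SD per coordinate (mm)
#' @param seed integer seed
#' @return long data.frame: id, population, observer, replicate, landmark,
#'   x, y, z
#' @export
simulateLandmarks <- function(nInd, popOffsets = NULL, noiseSd = 0.5,
                              nObservers = 2, nReps = 3, subjectSd = 1.5,
                              seed = 1) {
  stopifnot(nInd >= 1, nObservers >= 1, nReps >= 1, noiseSd >= 0)
  set.seed(as.integer(seed))
  tmpl <- noseTemplate()
  lms <- rownames(tmpl)
  pops <- if (is.null(popOffsets)) "pop1" else names(popOffsets)
  popOf <- rep_len(pops, nInd)

  rows <- vector("list", nInd)
  for (i in seq_len(nInd)) {
    subj <- tmpl + matrix(rnorm(21, 0, subjectSd), 7, 3)
    if (!is.null(popOffsets)) {
      off <- popOffsets[[popOf[i]]]
      for (lm in names(off)) subj[lm, ] <- subj[lm, ] + off[[lm]]
    }
    reps <- expand.grid(observer = seq_len(nObservers),
                        replicate = seq_len(nReps))
    block <- do.call(rbind, lapply(seq_len(nrow(reps)), function(j) {
      placed <- subj + matrix(rnorm(21, 0, noiseSd), 7, 3)
      data.frame(id = paste0("ind", i), population = popOf[i],
                 observer = paste0("obs", reps$observer[j]),
                 replicate = reps$replicate[j], landmark = lms,
                 x = placed[, 1], y = placed[, 2], z = placed[, 3],
                 stringsAsFactors = FALSE)
    }))
    rows[[i]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate per-individual climate values
#'
#' Each individual receives their population's long-term mean temperature,
#' vapor pressure and UVB irradiance plus independent Gaussian noise;
#' relative and absolute humidity are derived from temperature and vapor
#' pressure. Defaults emulate the four study regions (tropical West Africa,
#' temperate East Asia, Northern Europe, South Asia).
#'
#' @param pheno phenotype data.frame with \code{id} and \code{population}
#' @param popClimate data.frame with columns population, temperature (deg C),
#'   vapor_pressure (hPa), uvb (J/m2); default covers populations
#'   pop1..pop4
#' @param withinSd named noise SDs for the three primary variables
#' @param seed integer seed
#' @return climate data.frame keyed by \code{id} with temperature,
#'   vapor_pressure, uvb, relative_humidity, absolute_humidity
#' @export
simulateClimate <- function(pheno,
                            popClimate = data.frame(
                              population = paste0("pop", 1:4),
                              temperature = c(27, 12, 8, 25),
                              vapor_pressure = c(28, 12, 9, 22),
                              uvb = c(4500, 2800, 1500, 4200)),
                            withinSd = c(temperature = 1,
                                         vapor_pressure = 1, uvb = 100),
                            seed = 1) {
  stopifnot(all(c("id", "population") %in% names(pheno)))
  if (!all(pheno$population %in% popClimate$population))
    stop("popClimate lacks a row for population(s): ",
         paste(setdiff(pheno$population, popClimate$population),
               collapse = ", "))
  set.seed(as.integer(seed))
  idx <- match(pheno$population, popClimate$population)
  n <- nrow(pheno)
  temp <- popClimate$temperature[idx] + rnorm(n, 0, withinSd[["temperature"]])
  vp <- pmax(popClimate$vapor_pressure[idx] +
               rnorm(n, 0, withinSd[["vapor_pressure"]]), 0.1)
  vp <- pmin(vp, saturationVaporPressure(temp))   # cap at saturation
  uvb <- pmax(popClimate$uvb[idx] + rnorm(n, 0, withinSd[["uvb"]]), 0)
  data.frame(id = pheno$id, temperature = temp, vapor_pressure = vp,
             uvb = uvb,
             relative_humidity = relativeHumidity(vp, temp),
             absolute_humidity = absoluteHumidity(vp, temp),
             stringsAsFactors = FALSE)
}
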