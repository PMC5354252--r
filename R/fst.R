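## Weir & Cockerham (1984) theta for biallelic SNPs across labeled
## populations, with observed heterozygosity (no Hardy-Weinberg assumption)
## and diploid individuals.

#' Weir-Cockerham theta across populations
#'
#' Computes the per-SNP variance components \code{a} (among populations),
#' \code{b} (among individuals within populations) and \code{c} (within
#' individuals) of Weir & Cockerham's theta for every biallelic SNP, using
#' allele frequencies and observed heterozygote frequencies per population.
#' Per-SNP theta is \code{a/(a+b+c)}; the multi-locus estimate is the
#' ratio of sums \eqn{\sum a / \sum (a+b+c)} (not the mean of per-SNP
#' ratios). Negative per-SNP values are retained: downstream bootstrap
#' draws sample from the realized distribution.
#'
#' SNPs are excluded (and counted) when fewer than two populations have a
#' genotyped individual, when the locus is monomorphic across all
#' populations, or when the estimator is otherwise undefined (for example
#' a single genotyped individual per population).
#'
#' @param genos a \linkS4class{GenotypeMatrix}
#' @return a \linkS4class{FstDistribution}
#' @examples
#' # one SNP, two populations of four individuals each
#' d <- matrix(c(0, 1, 1, 2, 1, 2, 2, 2), nrow = 1)
#' g <- GenotypeMatrix(d, population = rep(c("A", "B"), each = 4))
#' multiLocusTheta(wcTheta(g))
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wcTheta <- function(genos) {
  stopifnot(is(genos, "GenotypeMatrix"))
  d <- dosage(genos)
  pop <- factor(population(genos))
  pops <- levels(pop)
  if (length(pops) < 2L) stop("need at least 2 populations")

  # per-SNP x per-population summaries (genotyped count, allele sum, het count)
  nMat <- sapply(pops, function(k)
    rowSums(!is.na(d[, pop == k, drop = FALSE])))
  sMat <- sapply(pops, function(k)
    rowSums(d[, pop == k, drop = FALSE], na.rm = TRUE))
  hMat <- sapply(pops, function(k)
    rowSums(d[, pop == k, drop = FALSE] == 1, na.rm = TRUE))
  if (nrow(d) == 1L) {  # sapply drops to vectors for a single SNP
    nMat <- matrix(nMat, 1); sMat <- matrix(sMat, 1); hMat <- matrix(hMat, 1)
  }

  present <- nMat > 0
  r <- rowSums(present)                      # populations observed per SNP
  pMat <- ifelse(present, sMat / (2 * pmax(nMat, 1L)), NA)
  hbarMat <- ifelse(present, hMat / pmax(nMat, 1L), NA)

  nTot <- rowSums(nMat)                      # total genotyped individuals
  nbar <- nTot / r
  nc <- (nTot - rowSums(nMat^2) / nTot) / (r - 1)
  pbar <- rowSums(nMat * pMat, na.rm = TRUE) / nTot
  s2 <- rowSums(nMat * (pMat - pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- rowSums(nMat * hbarMat, na.rm = TRUE) / nTot

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc

  usable <- r >= 2 & is.finite(a) & is.finite(tot) & tot != 0
  nExcluded <- sum(!usable)
  if (!any(usable))
    stop("no usable SNPs: all loci monomorphic or undefined")

  perSnp <- data.frame(snp = rownames(d)[usable],
                       a = a[usable], d = tot[usable],
                       theta = (a / tot)[usable],
                       stringsAsFactors = FALSE)
  if (nExcluded > 0)
    message(nExcluded, " SNP(s) excluded (monomorphic or undefined theta)")
  new("FstDistribution", perSnp = perSnp,
      multiLocus = sum(perSnp$a) / sum(perSnp$d),
      nUsed = as.integer(nrow(perSnp)), nExcluded = as.integer(nExcluded))
}
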