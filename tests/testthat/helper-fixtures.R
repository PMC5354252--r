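# Shared fixtures and independent oracles, built in code.

# Toy six-value two-group data: hand ANOVA gives MSB 13.5, MSW 1, n0 3.
toyAnovaData <- function() {
  data.frame(population = rep(c("A", "B"), each = 3), y = c(1, 2, 3, 4, 5, 6))
}

# One-SNP genotype matrix from per-population dosage vectors.
toyGenotypes <- function(...) {
  popDosages <- list(...)
  GenotypeMatrix(matrix(unlist(popDosages), nrow = 1),
                 population = rep(paste0("pop", seq_along(popDosages)),
                                  lengths(popDosages)))
}

# Independent scalar transcription of the Weir & Cockerham (1984) a/b/c
# variance components for one biallelic locus: a deliberately literal,
# loop-based implementation kept separate from the package's vectorized
# estimator.
wcOracle <- function(popDosages) {
  r <- length(popDosages)
  n <- sapply(popDosages, length)
  p <- sapply(popDosages, function(d) sum(d) / (2 * length(d)))
  h <- sapply(popDosages, function(d) mean(d == 1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Identity kinship with ids.
identityKinship <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  KinshipMatrix(K)
}

# Rotation matrix about the z axis.
rotZ <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# A small structured cohort for climate tests: three populations with a
# temperature gradient and a trait generated with a known slope.
climateCohort <- function(n_per_pop = 40, slope = 0.1, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_pop
  pheno <- data.frame(
    id = paste0("i", seq_len(n)),
    population = rep(c("A", "B", "C"), each = n_per_pop),
    age = runif(n, 20, 40), bmi = rnorm(n, 24, 3),
    stringsAsFactors = FALSE)
  climate <- data.frame(
    id = pheno$id,
    temperature = rnorm(n, rep(c(5, 15, 25), each = n_per_pop), 2),
    stringsAsFactors = FALSE)
  pheno$trait <- 30 + slope * climate$temperature + 0.02 * pheno$age +
    rnorm(n, 0, 1)
  list(pheno = pheno, climate = climate)
}
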