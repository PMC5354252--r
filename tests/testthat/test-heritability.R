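test_that("GRM has the standardization properties", {
  cfg <- simConfig(nPops = 1, nPerPop = 80, nSnps = 1500, targetFst = 0,
                   sigma2gb = 0, c = 0, seed = 31)
  g <- simulateGenotypes(cfg)
  K <- grm(g)
  M <- K@nMarkers
  km <- kinship(K)
  expect_equal(mean(diag(km)), 1, tolerance = 3 / sqrt(M))
  off <- km[upper.tri(km)]
  expect_lt(abs(mean(off)), 0.02)
  expect_equal(sd(off), 1 / sqrt(M), tolerance = 0.3)
})

test_that("a duplicated individual has pairwise kinship near the diagonal", {
  cfg <- simConfig(nPops = 1, nPerPop = 40, nSnps = 800, targetFst = 0,
                   sigma2gb = 0, c = 0, seed = 32)
  d <- dosage(simulateGenotypes(cfg))
  d <- cbind(d, d[, 1])
  g <- GenotypeMatrix(d, population = rep("A", ncol(d)))
  km <- kinship(grm(g))
  n <- ncol(d)
  expect_equal(km[1, n], km[1, 1], tolerance = 1e-8)
})

test_that("monomorphic and missing dosages are handled", {
  d <- rbind(rep(1, 6) + c(0, 1, -1, 0, 1, -1), rep(2, 6))
  d[1, 2] <- NA
  g <- GenotypeMatrix(d, population = rep("A", 6))
  K <- grm(g)
  expect_equal(K@nMarkers, 1L)          # monomorphic SNP skipped
  expect_false(anyNA(kinship(K)))
  allMono <- GenotypeMatrix(rbind(rep(0, 4)), population = rep("A", 4))
  expect_error(grm(allMono), "monomorphic")
})

test_that("ancestry GRM rejects invariant tracts and tracks genotype GRM", {
  la0 <- LocalAncestryMatrix(matrix(1, 50, 10))
  expect_error(ancestryGrm(la0), "degenerate")
  sim <- simulateAdmixedCohort(admixSimConfig(nInd = 120, nSnps = 600,
                                              seed = 33))
  Ky <- ancestryGrm(sim$la)
  Kg <- grm(sim$genotypes)
  r <- cor(kinship(Ky)[upper.tri(kinship(Ky))],
           kinship(Kg)[upper.tri(kinship(Kg))])
  expect_gt(r, 0.2)     # local ancestry drives part of the genotype sharing
  expect_lt(r, 0.99)    # but not all of it
})

test_that("top PCs separate a two-block kinship and have fixed signs", {
  blocks <- rep(c(0, 1), each = 20)
  K <- KinshipMatrix(diag(40) * 0.8 + outer(blocks, blocks, "==") * 0.2)
  p1 <- topPCs(K, 2)
  p2 <- topPCs(K, 2)
  expect_identical(p1, p2)
  expect_gt(abs(mean(p1[blocks == 0, 1]) - mean(p1[blocks == 1, 1])),
            5 * sd(tapply(p1[, 1], blocks, sd)))
  expect_error(topPCs(K, 40), "smaller")
})

test_that("REML on pure noise estimates h2 near zero", {
  cfg <- simConfig(nPops = 1, nPerPop = 150, nSnps = 400, targetFst = 0,
                   sigma2gb = 0, c = 0, seed = 34)
  K <- grm(simulateGenotypes(cfg))
  h <- vapply(1:50, function(s) {
    set.seed(200 + s)
    remlH2(rnorm(150), NULL, K)@h2
  }, numeric(1))
  expect_lt(median(h), 0.05)
})

test_that("REML recovers a generating h2 of 0.5 within 2 SE", {
  cfg <- simConfig(nPops = 1, nPerPop = 500, nSnps = 2000, targetFst = 0,
                   sigma2gb = 0, sigma2gw = 1, h2 = 0.5, c = 0, seed = 35)
  g <- simulateGenotypes(cfg)
  ph <- simulatePhenotype(g, cfg)
  est <- remlH2(ph$trait, ph[, c("sex", "age", "bmi")], grm(g))
  expect_equal(est@kind, "h_g2")
  expect_lt(abs(est@h2 - 0.5), 2 * est@se)
  expect_gt(est@se, 0)
})

test_that("REML estimate is invariant to shifting y and reparameterizing X", {
  cfg <- simConfig(nPops = 1, nPerPop = 120, nSnps = 500, targetFst = 0,
                   sigma2gb = 0, sigma2gw = 1, h2 = 0.4, c = 0, seed = 36)
  g <- simulateGenotypes(cfg)
  ph <- simulatePhenotype(g, cfg)
  K <- grm(g)
  X <- cbind(age = ph$age, bmi = ph$bmi)
  a <- remlH2(ph$trait, X, K)
  b <- remlH2(ph$trait + 100, X, K)
  # invertible reparameterization of the covariate space
  Xr <- cbind(s = X[, 1] + X[, 2], d = 2 * X[, 1] - X[, 2])
  c3 <- remlH2(ph$trait, Xr, K)
  expect_equal(a@h2, b@h2, tolerance = 1e-6)
  expect_equal(a@h2, c3@h2, tolerance = 1e-5)
})

test_that("the returned h2 is a local optimum of the REML objective", {
  cfg <- simConfig(nPops = 1, nPerPop = 100, nSnps = 400, targetFst = 0,
                   sigma2gb = 0, sigma2gw = 1, h2 = 0.5, c = 0, seed = 37)
  g <- simulateGenotypes(cfg)
  ph <- simulatePhenotype(g, cfg)
  K <- grm(g)
  est <- remlH2(ph$trait, NULL, K)
  rot <- qstfst:::rotateByKinship(ph$trait,
                                  matrix(1, length(ph$trait), 1),
                                  kinship(K))
  llAt <- function(h) qstfst:::profileLogLik(h, rot, reml = TRUE)
  for (h in c(max(est@h2 - 0.05, 0), min(est@h2 + 0.05, 0.999)))
    expect_gte(est@logLik, llAt(h) - 1e-6)
})

test_that("h_y2 recovery on an admixed cohort lies within 2 SE", {
  sim <- simulateAdmixedCohort(admixSimConfig(nInd = 400, nSnps = 1500,
                                              hy2Target = 0.22, seed = 38))
  est <- remlH2(sim$pheno$trait,
                data.frame(age = sim$pheno$age, bmi = sim$pheno$bmi,
                           ancestry = sim$pheno$globalAncestry),
                ancestryGrm(sim$la))
  expect_equal(est@kind, "h_y2")
  expect_lt(abs(est@h2 - 0.22), 2 * est@se)
})
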