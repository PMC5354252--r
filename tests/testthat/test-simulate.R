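test_that("seeded simulation is bit-reproducible", {
  cfg <- simConfig(nPops = 2, nPerPop = 20, nSnps = 100, targetFst = 0.1,
                   seed = 5)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(dosage(g1), dosage(g2))
  p1 <- simulatePhenotype(g1, cfg)
  p2 <- simulatePhenotype(g2, cfg)
  expect_identical(p1$trait, p2$trait)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(targetFst = 1), "targetFst")
  expect_error(simConfig(mafRange = c(0, 0)), "mafRange")
  expect_error(simConfig(h2 = 1.2), "h2")
  expect_error(simConfig(sigma2gb = 0, c = 0.5), "sigma2gb")
  expect_error(simConfig(nPerPop = 0), "positive")
  expect_error(admixSimConfig(ancestryMean = 1), "ancestryMean")
  expect_error(admixSimConfig(tractMeanSnps = 0.5), "tractMeanSnps")
})

test_that("dosages are valid and population labels attached", {
  cfg <- simConfig(nPops = 3, nPerPop = c(5, 8, 11), nSnps = 50, seed = 2)
  g <- simulateGenotypes(cfg)
  expect_true(all(dosage(g) %in% 0:2))
  expect_equal(unname(table(population(g))[paste0("pop", 1:3)]),
               c(5L, 8L, 11L), ignore_attr = TRUE)
})

test_that("no between-population variance yields near-zero Qst estimates", {
  qs <- vapply(1:200, function(s) {
    cfg <- simConfig(nPops = 4, nPerPop = 100, nSnps = 10, targetFst = 0,
                     sigma2gb = 0, sigma2gw = 1, h2 = 0.5, c = 0, seed = s)
    ph <- simulatePhenotype(simulateGenotypes(cfg), cfg)
    qstValue(suppressMessages(varianceComponents(ph, "trait")))$qst
  }, numeric(1))
  expect_gte(mean(qs < 0.05), 0.95)
})

test_that("realized Qst matches the value implied by the components", {
  # equal components with c = h2: expected Qst = 1/3
  qs <- vapply(1:200, function(s) {
    cfg <- simConfig(nPops = 4, nPerPop = 100, nSnps = 150, targetFst = 0.1,
                     sigma2gb = 1, sigma2gw = 1, h2 = 0.5, c = 0.5, seed = s)
    ph <- simulatePhenotype(simulateGenotypes(cfg), cfg)
    qstValue(varianceComponents(ph, "trait"))$qst
  }, numeric(1))
  expect_lt(abs(mean(qs) - 1 / 3), 0.03)

  # components tuned so the true Qst is 0.64
  qs2 <- vapply(1:200, function(s) {
    cfg <- simConfig(nPops = 4, nPerPop = 100, nSnps = 150, targetFst = 0.1,
                     sigma2gb = 0.64 * 2 / 0.36, sigma2gw = 1, h2 = 0.5,
                     c = 0.5, seed = 5000 + s)
    ph <- simulatePhenotype(simulateGenotypes(cfg), cfg)
    qstValue(varianceComponents(ph, "trait"))$qst
  }, numeric(1))
  expect_lt(abs(mean(qs2) - 0.64), 0.05)
})

test_that("admixed cohort: local ancestry averages to global ancestry", {
  # a dense panel with short tracts, so realized tract noise is small
  cfg <- admixSimConfig(nInd = 150, nSnps = 4000, tractMeanSnps = 5,
                        seed = 3)
  sim <- simulateAdmixedCohort(cfg)
  expect_true(all(ancestryDosage(sim$la) %in% 0:2))
  # row-mean/2 reproduces the phenotype table's global ancestry exactly
  expect_equal(unname(globalAncestry(sim$la)), sim$pheno$globalAncestry,
               tolerance = 1e-12)
  # and correlates near-perfectly with the Beta draw that generated it
  set.seed(3)
  qDrawn <- pmin(pmax(rbeta(150, 0.6 * 8, 0.4 * 8), 0.02), 0.98)
  expect_gt(cor(globalAncestry(sim$la), qDrawn)^2, 0.99)
})

test_that("ancestry-free traits yield near-zero h_y2 estimates", {
  hy <- vapply(1:50, function(s) {
    cfg <- admixSimConfig(nInd = 200, nSnps = 300, hy2Target = 0,
                          seed = 100 + s)
    sim <- simulateAdmixedCohort(cfg)
    remlH2(sim$pheno$trait,
           data.frame(ancestry = sim$pheno$globalAncestry),
           ancestryGrm(sim$la))@h2
  }, numeric(1))
  expect_lt(median(hy), 0.05)
})

test_that("population-specific landmark offsets surface only in the
           targeted trait", {
  offs <- list(pop1 = list(),
               pop2 = list(al_l = c(-2.5, 0, 0), al_r = c(2.5, 0, 0)))
  lt <- simulateLandmarks(160, popOffsets = offs, noiseSd = 0.2, seed = 11)
  traits <- averageReplicates(replicateDistances(lt))
  pops <- unique(lt[, c("id", "population")])
  traits$population <- pops$population[match(traits$id, pops$id)]
  qst <- vapply(c("nares_width", "alar_base_width", "nasal_height",
                  "nasal_ridge_length", "nasal_tip_protrusion"),
                function(tr)
                  qstValue(suppressMessages(
                    varianceComponents(traits, tr,
                                       covariates = character(0))))$qst,
                numeric(1))
  expect_gt(qst[["nares_width"]], 0.5)
  expect_true(all(qst[names(qst) != "nares_width"] < 0.2))
})

test_that("climate generator degenerates to shared values at zero spread", {
  ph <- data.frame(id = paste0("i", 1:30),
                   population = rep(paste0("pop", 1:3), each = 10))
  cl <- simulateClimate(ph, withinSd = c(temperature = 0,
                                         vapor_pressure = 0, uvb = 0),
                        seed = 1)
  byPop <- split(cl$temperature, ph$population)
  expect_true(all(vapply(byPop, function(x) diff(range(x)) == 0,
                         logical(1))))
  expect_true(all(cl$relative_humidity > 0 & cl$relative_humidity <= 100))
  expect_error(simulateClimate(data.frame(id = "a", population = "zzz")),
               "zzz")
})
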