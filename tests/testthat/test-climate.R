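test_that("Magnus saturation vapor pressure matches reference points", {
  expect_equal(saturationVaporPressure(0), 6.1094)
  expect_equal(saturationVaporPressure(20), 23.34, tolerance = 1e-3)
  Ts <- seq(-30, 40, by = 5)
  expect_true(all(diff(saturationVaporPressure(Ts)) > 0))
  expect_error(saturationVaporPressure(-250), "-243.04")
})

test_that("relative humidity is the saturation ratio, capped at 100", {
  expect_equal(relativeHumidity(saturationVaporPressure(15), 15), 100)
  expect_equal(relativeHumidity(10, 20), 42.855, tolerance = 1e-3)
  expect_equal(relativeHumidity(0, 20), 0)
  expect_warning(rh <- relativeHumidity(30, 20), "capped")
  expect_equal(rh, 100)
  expect_error(relativeHumidity(-1, 20), "non-negative")
})

test_that("absolute humidity follows the ideal-gas form", {
  expect_equal(absoluteHumidity(10, 20), 7.392, tolerance = 1e-3)
  expect_equal(absoluteHumidity(0, 20), 0)
  es <- seq(1, 30, by = 1)
  expect_true(all(diff(absoluteHumidity(es, 20)) > 0))
})

test_that("ancestral climate averages the available parents", {
  a <- data.frame(id = c("x", "y", "z"), temperature = c(10, 5, NA))
  b <- data.frame(id = c("x", "y", "z"), temperature = c(20, 5, 8))
  out <- ancestralClimate(a, b)
  expect_equal(out$temperature[out$id == "x"], 15)   # mean of 10 and 20
  expect_equal(out$temperature[out$id == "y"], 5)    # identical parents
  expect_equal(out$temperature[out$id == "z"], 8)    # single parent
})

test_that("with identity kinship the LMM slope equals OLS", {
  cc <- climateCohort(seed = 41)
  K <- identityKinship(cc$pheno$id)
  r <- kinshipLmmSlope(cc$pheno, cc$climate, "trait", "temperature", K = K)
  d <- cbind(cc$pheno, temperature = cc$climate$temperature)
  ols <- lm(trait ~ temperature + age + bmi, data = d)
  expect_lt(abs(r@slope - coef(ols)[["temperature"]]), 1e-8)
  expect_gte(r@lrt, 0)
  expect_gt(r@pValue, 0)
})

test_that("a generating slope of 0.1 per degree is recovered within 2 SE", {
  # generate from the fitted model itself: within-population polygenic
  # signal plus climate effect, no extra population-level trait variance
  cfg <- simConfig(nPops = 4, nPerPop = 35, nSnps = 600, targetFst = 0.12,
                   sigma2gb = 0, sigma2gw = 0.5, h2 = 0.5, c = 0,
                   covariateEffects = c(sex = 0, age = 0.05, bmi = 0.1),
                   seed = 42)
  g <- simulateGenotypes(cfg)
  ph <- simulatePhenotype(g, cfg)
  cl <- simulateClimate(ph, seed = 43)
  ph$trait <- ph$trait + 0.1 * cl$temperature
  r <- kinshipLmmSlope(ph, cl, "trait", "temperature", K = grm(g))
  expect_lt(abs(r@slope - 0.1), 2 * r@se)
})

test_that("permuted climate labels give approximately uniform LRT p-values", {
  cfg <- simConfig(nPops = 4, nPerPop = 35, nSnps = 600, targetFst = 0.12,
                   sigma2gb = 1, sigma2gw = 1, h2 = 0.5, c = 0.5, seed = 44)
  g <- simulateGenotypes(cfg)
  ph <- simulatePhenotype(g, cfg)
  K <- grm(g)
  cl <- simulateClimate(ph, seed = 45)
  set.seed(46)
  ps <- vapply(1:200, function(r) {
    clp <- cl
    clp$temperature <- sample(clp$temperature)
    kinshipLmmSlope(ph, clp, "trait", "temperature", K = K)@pValue
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("leave-one-population-out isolates the population carrying the
           climate contrast", {
  # populations A and B share one climate; C carries all the contrast and
  # all of the trait difference
  set.seed(47)
  n <- 120
  ph <- data.frame(id = paste0("i", seq_len(n)),
                   population = rep(c("A", "B", "C"), each = 40),
                   age = runif(n, 20, 40), bmi = rnorm(n, 24, 3))
  popMeanTemp <- rep(c(10, 10, 25), each = 40)
  cl <- data.frame(id = ph$id,
                   temperature = rnorm(n, popMeanTemp, 1))
  # trait tracks the population-level climate only, so populations A and B
  # carry no climate-trait signal between them
  ph$trait <- 30 + 0.3 * popMeanTemp + rnorm(n, 0, 1)
  K <- identityKinship(ph$id)
  tab <- leaveOnePopulationOut(ph, cl, "trait", "temperature", K = K)
  expect_equal(tab$dropped, c("none", "A", "B", "C"))
  full <- kinshipLmmSlope(ph, cl, "trait", "temperature", K = K)
  expect_equal(tab$slope[tab$dropped == "none"], full@slope)
  expect_true(tab$overlapsZero[tab$dropped == "C"])
  expect_false(any(tab$overlapsZero[tab$dropped %in% c("none", "A", "B")]))
})

test_that("degenerate climate designs are rejected", {
  cc <- climateCohort(seed = 48)
  K <- identityKinship(cc$pheno$id)
  clConst <- cc$climate
  clConst$temperature <- 7
  expect_error(kinshipLmmSlope(cc$pheno, clConst, "trait", "temperature",
                               K = K), "constant climate")
  expect_error(kinshipLmmSlope(cc$pheno, cc$climate, "trait", "nope",
                               K = K), "not found")
})
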