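# helper: a QstBootstrap with prescribed per-draw components
fixedBootstrap <- function(spb, spw, trait = "t") {
  obs <- suppressMessages(varianceComponents(toyAnovaData(), "y",
                                             covariates = character(0)))
  new("QstBootstrap", trait = trait, observed = obs,
      sigma2pbDraws = spb, sigma2pwDraws = spw,
      nBoot = length(spb), seed = 1L,
      strata = data.frame(stratum = "all", size = length(spb)))
}

test_that("bootstrap is deterministic and preserves stratum structure", {
  set.seed(8)
  n <- 120
  ph <- data.frame(id = seq_len(n),
                   population = rep(c("A", "B", "C"), each = 40),
                   sex = rep(c("male", "female"), 60),
                   age = runif(n, 18, 40), bmi = rnorm(n, 24, 3))
  ph$trait <- rnorm(n, rep(c(0, 1, 2), each = 40))
  b1 <- bootstrapQst(ph, "trait", nBoot = 50, seed = 7)
  b2 <- bootstrapQst(ph, "trait", nBoot = 50, seed = 7)
  expect_identical(b1@sigma2pbDraws, b2@sigma2pbDraws)
  expect_identical(b1@sigma2pwDraws, b2@sigma2pwDraws)
  # strata recorded as population x sex with the observed sizes
  expect_equal(sum(b1@strata$size), n)
  expect_equal(nrow(b1@strata), 6L)
  # observed components equal a direct call
  vc <- varianceComponents(ph, "trait")
  expect_equal(b1@observed@sigma2pb, vc@sigma2pb)
})

test_that("a singleton stratum resamples to itself without error", {
  ph <- data.frame(population = rep(c("A", "B"), c(21, 20)),
                   sex = c(rep(c("male", "female"), c(1, 20)),
                           rep("female", 20)))
  set.seed(2)
  ph$trait <- rnorm(41) + 10 * (ph$sex == "male")
  b <- bootstrapQst(ph, "trait", covariates = "sex", nBoot = 30, seed = 3)
  expect_length(b@sigma2pbDraws, 30)
  expect_true(all(is.finite(b@sigma2pwDraws)))
  expect_true(1L %in% b@strata$size)
})

test_that("empirical p is the share of negative Qst-Fst differences", {
  b <- fixedBootstrap(spb = rep(c(1, 0), c(60, 40)), spw = rep(1, 100))
  fd <- new("FstDistribution",
            perSnp = data.frame(snp = "s1", a = 0.1, d = 1, theta = 0.1),
            multiLocus = 0.1, nUsed = 1L, nExcluded = 0L)
  tst <- qstFstTest(b, fd, seed = 1)
  # Qst draws are 1/3 (60 draws) and 0 (40 draws); fst is always 0.1
  expect_equal(empiricalP(tst), 0.4)
  expect_false(tst@pIsUpperBound)
  expect_equal(empiricalP(tst), mean(qstDraws(tst) - fstDraws(tst) < 0))
})

test_that("a zero proportion is reported as bounded by 1/nBoot", {
  b <- fixedBootstrap(spb = rep(1, 200), spw = rep(1, 200))
  fd <- new("FstDistribution",
            perSnp = data.frame(snp = "s1", a = 0, d = 1, theta = 0),
            multiLocus = 0, nUsed = 1L, nExcluded = 0L)
  tst <- qstFstTest(b, fd, seed = 1)
  expect_true(tst@pIsUpperBound)
  expect_equal(empiricalP(tst), 1 / 200)
})

test_that("Bonferroni flags use a strict threshold", {
  rep7 <- bonferroniReport(c(a = 0.0070, b = 0.05 / 7, c = 0.5),
                           alpha = 0.05, nTests = 7)
  expect_equal(rep7$threshold[1], 0.0071428571, tolerance = 1e-8)
  expect_equal(rep7$accelerated, c(TRUE, FALSE, FALSE))
  rep1 <- bonferroniReport(c(x = 0.049), nTests = 1)
  expect_true(rep1$accelerated)
  expect_error(bonferroniReport(c(1.2)), "0, 1")
})

test_that("noise-free sensitivity curve recovers the algebraic critical
           ratio within one grid step", {
  # r* solves r spb / (r spb + 2 spw) = f  =>  r* = 2 f spw / (spb (1 - f))
  grid <- seq(0.01, 1, by = 0.01)
  for (case in list(c(spb = 1, spw = 1, f = 0.2),
                    c(spb = 2, spw = 0.5, f = 0.12),
                    c(spb = 0.8, spw = 1.2, f = 0.25))) {
    b <- fixedBootstrap(spb = rep(case[["spb"]], 50),
                        spw = rep(case[["spw"]], 50))
    sc <- sensitivityCurve(b, rep(case[["f"]], 50), grid = grid)
    rStar <- 2 * case[["f"]] * case[["spw"]] /
      (case[["spb"]] * (1 - case[["f"]]))
    expect_lte(abs(criticalRatio(sc) - rStar), 0.01 + 1e-9)
  }
})

test_that("a curve that never crosses is flagged above the grid", {
  b <- fixedBootstrap(spb = rep(0.1, 50), spw = rep(1, 50))
  sc <- sensitivityCurve(b, rep(0.3, 50))
  expect_true(sc@criticalAboveMax)
  expect_true(is.na(criticalRatio(sc)))
})

test_that("Qst quantiles rise with the ratio and the critical value falls
           as observed Qst grows", {
  set.seed(5)
  spw <- rep(1, 400)
  b1 <- fixedBootstrap(spb = rlnorm(400, log(0.6), 0.2), spw = spw)
  b2 <- fixedBootstrap(spb = rlnorm(400, log(1.8), 0.2), spw = spw)
  fstDraws <- rbeta(400, 2, 40)   # mean ~0.05
  s1 <- sensitivityCurve(b1, fstDraws)
  s2 <- sensitivityCurve(b2, fstDraws)
  expect_true(all(diff(s1@curve$qstLower) >= 0))
  expect_true(all(diff(s1@curve$qstUpper) >= 0))
  expect_false(s1@criticalAboveMax || s2@criticalAboveMax)
  expect_lt(criticalRatio(s2), criticalRatio(s1))
})

test_that("stored draws reproduce the reported p exactly", {
  set.seed(12)
  b <- fixedBootstrap(spb = rgamma(300, 2, 4), spw = rep(1, 300))
  fd <- new("FstDistribution",
            perSnp = data.frame(snp = paste0("s", 1:50),
                                a = rgamma(50, 1, 10), d = rep(1, 50),
                                theta = rbeta(50, 2, 10)),
            multiLocus = 0.15, nUsed = 50L, nExcluded = 0L)
  tst <- qstFstTest(b, fd, seed = 4)
  diffs <- qstDraws(tst) - fstDraws(tst)
  expect_equal(empiricalP(tst), ecdf(diffs)(0) - mean(diffs == 0))
})
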