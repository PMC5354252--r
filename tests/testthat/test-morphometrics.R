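test_that("landmark distances reproduce elementary geometry", {
  lm <- matrix(0, 7, 3,
               dimnames = list(c("n", "prn", "sn", "al_l", "al_r",
                                 "ac_l", "ac_r"), NULL))
  lm["al_r", ] <- c(3, 4, 0)
  d <- landmarkDistances(lm)
  expect_equal(d[["nares_width"]], 5)          # 3-4-5 triangle
  expect_equal(d[["alar_base_width"]], 0)      # coincident pair
  expect_error(landmarkDistances(lm[-4, , drop = FALSE]), "al_l")
})

test_that("distances are invariant to rigid motion", {
  set.seed(51)
  lm <- qstfst:::noseTemplate() + matrix(rnorm(21), 7, 3)
  moved <- lm %*% rotZ(1.1) + matrix(rep(c(10, -4, 2), each = 7), 7)
  rownames(moved) <- rownames(lm)
  expect_equal(landmarkDistances(lm), landmarkDistances(moved),
               tolerance = 1e-10)
})

test_that("Procrustes superimposition is rigid-invariant and idempotent", {
  set.seed(52)
  A <- matrix(rnorm(21), 7, 3)
  B <- A %*% rotZ(0.8) + matrix(rep(c(3, -2, 5), each = 7), 7)
  out <- procrustesAlign(list(A, B))
  expect_lt(sqrt(mean((out$aligned[, , 1] - out$aligned[, , 2])^2)), 1e-8)
  again <- procrustesAlign(list(out$aligned[, , 1], out$aligned[, , 2]))
  expect_lt(max(abs(again$aligned - out$aligned)), 1e-8)
  expect_error(procrustesAlign(list(matrix(1, 7, 3), A)), "degenerate")
  expect_error(procrustesAlign(list(A)), "at least 2")
})

test_that("the consensus of perturbed copies approaches the template", {
  tmpl <- qstfst:::noseTemplate()
  tmpl <- sweep(tmpl, 2, colMeans(tmpl))
  makeSet <- function(N, seed) {
    set.seed(seed)
    lapply(seq_len(N), function(i) tmpl + matrix(rnorm(21, 0, 1), 7, 3))
  }
  errFor <- function(N) {
    cons <- procrustesAlign(makeSet(N, 53))$consensus
    r <- procrustesAlign(list(cons, tmpl))
    sqrt(mean((r$aligned[, , 1] - r$aligned[, , 2])^2))
  }
  expect_lt(errFor(200), errFor(8))
  expect_lt(errFor(200), 0.15)
})

test_that("symmetrization halves asymmetry and fixes symmetric inputs", {
  tmpl <- qstfst:::noseTemplate()
  refl <- reflectConfig(tmpl)
  expect_equal(symmetrizeConfig(tmpl, refl), tmpl)   # already symmetric
  asym <- tmpl
  asym["al_l", 1] <- asym["al_l", 1] - 2   # displace 2 mm laterally
  sym <- symmetrizeConfig(asym, reflectConfig(asym))
  # the 2 mm widening is split: each side moves 1 mm outward symmetrically
  expect_equal(sym["al_l", 1], asym["al_l", 1] + 1)
  expect_equal(sym["al_r", 1], asym["al_r", 1] + 1)
  expect_equal(abs(unname(sym["al_l", 1])), abs(unname(sym["al_r", 1])))
  # midline landmarks land on the symmetry plane
  expect_lt(max(abs(sym[c("n", "prn", "sn"), 1])), 1e-8)
  # symmetrize of a symmetric configuration is a fixed point (idempotence)
  sym2 <- symmetrizeConfig(sym, reflectConfig(sym))
  expect_equal(sym2, sym, tolerance = 1e-12)
  expect_error(symmetrizeConfig(tmpl, refl,
                                pairing = c(al_l = "al_r", al_r = "ac_l",
                                            ac_l = "al_l")),
               "involution")
})

test_that("region areas sum triangle areas and ignore rigid motion", {
  tri <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
              faces = rbind(c(1, 2, 3)))
  expect_equal(regionArea(tri), 0.5)
  sq <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                              c(0, 1, 0)),
             faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(regionArea(sq), 1)
  rot <- list(vertices = sq$vertices %*% rotZ(0.3) +
                matrix(rep(c(5, 5, 5), each = 4), 4), faces = sq$faces)
  expect_lt(abs(regionArea(rot) - 1), 1e-10)
  expect_error(regionArea(sq, integer(0)), "empty region")
  expect_error(regionArea(sq, 1:2), "no complete triangle")
  areas <- meshAreas(sq, noseRegion = 1:4, nostrilLeft = c(1, 2, 3),
                     nostrilRight = c(1, 3, 4))
  expect_equal(areas[["external_surface_area"]], 1)
  expect_equal(areas[["nostril_area"]], 0.5)
})

test_that("melanin index transform and its inverse behave as specified", {
  expect_equal(melaninIndex(1), 0)
  expect_equal(melaninIndex(0.5), 30.103, tolerance = 1e-4)
  refl <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(melaninIndex(refl)) < 0))    # strictly decreasing
  expect_error(melaninIndex(0), "positive")
  expect_error(melaninIndex(-0.1), "positive")
  expect_error(melaninIndex(150), "100 percent")
  expect_warning(mi <- melaninIndex(50), "percent")
  expect_equal(mi, melaninIndex(0.5))
  expect_equal(meanMelaninIndex(rbind(c(0.5, 0.5, 0.5))),
               melaninIndex(0.5), ignore_attr = TRUE)
  expect_equal(inverseMelaninIndex(30.103), 1 / 30.103)
  expect_error(inverseMelaninIndex(0), "positive")
})

test_that("ICC is 1 with zero replicate noise and recovers a 9:1 design", {
  lt0 <- simulateLandmarks(25, noiseSd = 0, seed = 54)
  rd0 <- replicateDistances(lt0)
  r0 <- iccReliability(data.frame(subject = rd0$id, observer = rd0$observer,
                                  value = rd0$nares_width))
  expect_equal(r0$icc, 1)
  expect_equal(r0$varError, 0)

  # noiseSd = subjectSd / 3 gives subject:error variance 9:1 at the
  # distance level, hence ICC about 0.9
  lt <- simulateLandmarks(200, noiseSd = 0.5, subjectSd = 1.5, seed = 55)
  rd <- replicateDistances(lt)
  r <- iccReliability(data.frame(subject = rd$id, observer = rd$observer,
                                 value = rd$nares_width))
  expect_lt(abs(r$icc - 0.9), 0.03)
  expect_true(r$icc >= 0 && r$icc <= 1)
  expect_equal(nrow(r$intraObserver), 2L)
  expect_true(all(r$intraObserver$upper >= r$intraObserver$lower))
  expect_error(iccReliability(data.frame(subject = "a",
                                         observer = c("o1", "o2"),
                                         value = c(1, 2))),
               "single subject")
})

test_that("replicate averaging is within observer first, then across", {
  lt <- simulateLandmarks(10, noiseSd = 0.4, seed = 56)
  rd <- replicateDistances(lt)
  av <- averageReplicates(rd)
  one <- rd[rd$id == "ind1", ]
  manual <- mean(tapply(one$nares_width, one$observer, mean))
  expect_equal(av$nares_width[av$id == "ind1"], manual)
})
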