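test_that("every generator is bit-identical given its seed", {
  cfg <- simConfig("two_deme_island", nIndividuals = 8, nSnps = 100, seed = 7)
  g1 <- simGenotypes(cfg)
  g2 <- simGenotypes(cfg)
  expect_identical(genotypes(g1$gm), genotypes(g2$gm))
  expect_identical(sitePos(g1$gm), sitePos(g2$gm))
  s1 <- simBottleneckSFS(simConfig("bottleneck_B", nIndividuals = 10,
                                   nSnps = 500, seed = 3))
  s2 <- simBottleneckSFS(simConfig("bottleneck_B", nIndividuals = 10,
                                   nSnps = 500, seed = 3))
  expect_identical(sfsCounts(s1$sfs), sfsCounts(s2$sfs))
  h1 <- simHostSurvey(c(A = 100, B = 100), nAttacks = 50, seed = 5)
  h2 <- simHostSurvey(c(A = 100, B = 100), nAttacks = 50, seed = 5)
  expect_identical(h1$survey, h2$survey)
  p1 <- simSuitabilityPair("partial", seed = 9)
  p2 <- simSuitabilityPair("partial", seed = 9)
  expect_identical(p1, p2)
})

test_that("genotype generator honours missingness, positions and truth", {
  g0 <- simGenotypes(simConfig("panmictic", nIndividuals = 10, nSnps = 200,
                               missingness = 0, seed = 2))
  expect_false(anyNA(genotypes(g0$gm)))
  expect_equal(g0$truth$trueK, 1L)
  expect_true(all(diff(sitePos(g0$gm)) > 0))
  g5 <- simGenotypes(simConfig("panmictic", nIndividuals = 10, nSnps = 400,
                               missingness = 0.2, seed = 2))
  expect_gt(mean(is.na(genotypes(g5$gm))), 0.15)
  expect_lt(mean(is.na(genotypes(g5$gm))), 0.25)
  # every simulated site is polymorphic in the sample before missingness
  p <- colMeans(genotypes(g0$gm)) / 2
  expect_true(all(p > 0 & p < 1))
  g2d <- simGenotypes(simConfig("two_deme_island", nIndividuals = 8,
                                nSnps = 150, fst = 0.2, seed = 4))
  expect_equal(g2d$truth$trueK, 2L)
  expect_equal(g2d$truth$trueFst, 0.2)
  expect_equal(sort(unique(popLabels(g2d$gm))), c("deme1", "deme2"))
})

test_that("bottleneck SFS generator stores truth and sums to nSnps", {
  cfg <- simConfig("bottleneck_C", nIndividuals = 12, nSnps = 800,
                   nCur = 1e5, tBot = 1500, gR = -5e-3, seed = 6)
  out <- simBottleneckSFS(cfg)
  expect_equal(sum(sfsCounts(out$sfs)), 800)
  expect_equal(out$truth$params$tBot, 1500)
  expect_error(simBottleneckSFS(simConfig("panmictic")), "bottleneck")
})

test_that("host survey generator respects budgets, bounds and truth labels", {
  avail <- data.frame(site = rep(c("s1", "s2"), each = 2),
                      taxon = rep(c("A", "B"), 2),
                      available = c(50, 60, 70, 80))
  out <- simHostSurvey(avail, weights = c(A = 3, B = 0.5), nAttacks = 100,
                       seed = 8)
  expect_equal(sum(out$survey$attacked), 100)
  expect_true(all(out$survey$attacked <= out$survey$available))
  expect_equal(unname(out$truth$planted[c("A", "B")]),
               c("preference", "avoidance"))
  expect_error(simHostSurvey(avail, nAttacks = 0), "positive")
  expect_error(simHostSurvey(avail, nAttacks = 1e6), "exceeds")
  expect_error(simHostSurvey(avail, weights = c(A = -1, B = 1),
                             nAttacks = 10), "positive")
})

test_that("suitability pairs span the overlap regimes", {
  idp <- simSuitabilityPair("identical", seed = 1)
  expect_identical(idp$a, idp$b)
  dis <- simSuitabilityPair("disjoint", seed = 1)
  expect_equal(sum(dis$a * dis$b), 0)
  par <- simSuitabilityPair("partial", mixing = 0.5, seed = 1)
  D <- schoenersD(par$a, par$b)
  expect_gt(D, 0)
  expect_lt(D, 1)
  expect_true(all(par$a >= 0 & par$a <= 1))
})
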