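test_that("size trajectories implement the four model shapes", {
  mA <- demographicModel("A", nCur = 5e4)
  NA_ <- sizeTrajectory(mA)
  expect_equal(NA_(c(0, 10, 1e6)), rep(5e4, 3))
  # step sizes at the published point estimates
  mB <- demographicModel("B", nCur = 206750)
  NB <- sizeTrajectory(mB, c(nAnc = 1044983, tBot = 114))
  expect_equal(NB(100), 206750)
  expect_equal(NB(200), 1044983)
  # C with zero growth reduces to B
  mC <- demographicModel("C", nCur = 206750)
  NC <- sizeTrajectory(mC, c(nAnc = 1044983, tBot = 114, gR = 0))
  tt <- c(0, 50, 113.9, 114, 500)
  expect_equal(NC(tt), NB(tt))
  # D: three levels and the ordering constraint
  mD <- demographicModel("D", nCur = 1e4)
  ND <- sizeTrajectory(mD, c(nAnc = 1e5, nBot = 500, tBot = 300,
                             tEndBot = 50))
  expect_equal(ND(c(10, 100, 400)), c(1e4, 500, 1e5))
  expect_error(sizeTrajectory(mD, c(nAnc = 1e5, nBot = 500, tBot = 50,
                                    tEndBot = 300)), "tEndBot")
  expect_error(sizeTrajectory(mB, c(nAnc = -5, tBot = 100)), "positive")
})

test_that("simulated folded SFS sums to the SNP count and matches theory", {
  m <- demographicModel("A", nCur = 1e5)
  s <- simulateSFS(m, numeric(0), 12, 3000, seed = 2)
  expect_equal(sum(sfsCounts(s)), 3000)
  expect_equal(sfsCounts(s)[1], 0)  # no monomorphic class from SNP loci
  gof <- chisq.test(sfsCounts(s)[-1], p = foldedNeutralExpectation(12))
  expect_gt(gof$p.value, 0.01)
})

test_that("pairwise coalescence times average 2N under constant size", {
  m <- demographicModel("A", nCur = 5e4)
  tt <- pairCoalescenceTimes(m, numeric(0), 10000, seed = 3)
  se <- sd(tt) / sqrt(length(tt))
  expect_lt(abs(mean(tt) - 2 * 5e4), 3 * se)
})

test_that("analytic expected SFS matches the closed form and the MC engine", {
  m <- demographicModel("A", nCur = 3e4)
  p <- expectedSFS(m, numeric(0), 15)
  expect_equal(p, foldedNeutralExpectation(15), tolerance = 1e-8)
  mB <- demographicModel("B", nCur = 2000)
  pars <- c(nAnc = 1e4, tBot = 200)
  pa <- expectedSFS(mB, pars, 15)
  ps <- expectedSFS(mB, pars, 15, engine = "simulation", nSims = 6e4,
                    seed = 4)
  expect_lt(max(abs(pa - ps)), 0.01)
  expect_equal(sum(pa), 1)
  # a recent severe bottleneck leaves an excess of rare variants
  pBot <- expectedSFS(demographicModel("C", nCur = 1e5,
                                       bounds = list(gR = c(-1, 0))),
                      c(nAnc = 5e5, tBot = 1500, gR = -6e-3), 15)
  pConst <- foldedNeutralExpectation(15)
  expect_gt(pBot[1] + pBot[2], pConst[1] + pConst[2])
})

test_that("composite log-likelihood is a floored multinomial at its maximum", {
  m <- c(0, 120, 60, 40, 30, 25, 25)  # classes 0..6, n = 6
  obs <- FoldedSFS(m, 6)
  pHat <- m[-1] / sum(m[-1])
  lmax <- compositeLogLik(obs, pHat)
  expect_equal(lmax, sum(m[-1] * log(pHat)))
  # any other proportion vector does worse
  set.seed(5)
  for (i in 1:20) {
    p <- runif(6); p <- p / sum(p)
    expect_lte(compositeLogLik(obs, p), lmax)
  }
  # agreement with the multinomial pmf up to the combinatorial constant
  p <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  const <- lgamma(sum(m[-1]) + 1) - sum(lgamma(m[-1] + 1))
  expect_equal(compositeLogLik(obs, p),
               dmultinom(m[-1], prob = p, log = TRUE) - const,
               tolerance = 1e-10)
  # shifting observed mass onto a floored class lowers the likelihood
  pz <- c(0.5, 0.3, 0.2, 0, 0, 0)
  mShift <- c(0, 110, 60, 40, 30, 25, 35)
  expect_lt(compositeLogLik(FoldedSFS(mShift, 6), pz),
            compositeLogLik(obs, pz))
  expect_error(compositeLogLik(FoldedSFS(rep(0, 7), 6), pHat), "polymorphic")
})

test_that("fitting recovers bottleneck parameters and respects nesting", {
  mB <- demographicModel("B", nCur = 2000)
  truth <- c(nAnc = 1e4, tBot = 200)
  obs <- simulateSFS(mB, truth, 20, 4000, seed = 6)
  fit <- fitModel(obs, mB, nReps = 3, seed = 7)
  expect_gt(fit$paramsHat["tBot"], 100)
  expect_lt(fit$paramsHat["tBot"], 400)
  # more free parameters can never reduce the attainable likelihood
  mA <- demographicModel("A", nCur = 2000)
  fitA <- fitModel(obs, mA, seed = 7)
  expect_gte(fit$lnL, fitA$lnL - 1e-6)
  expect_equal(fitA$aic, -2 * fitA$lnL)  # zero free parameters
  # a model-A fit to model-A data reproduces the true-parameter likelihood
  obsA <- simulateSFS(mA, numeric(0), 20, 4000, seed = 8)
  fitAA <- fitModel(obsA, mA, seed = 1)
  expect_equal(fitAA$lnL,
               compositeLogLik(obsA, expectedSFS(mA, numeric(0), 20)))
})

test_that("AIC differences, weights, selection frequencies and joint support", {
  mk <- function(id, aic, repAics) {
    list(modelId = id, k = 1L, lnL = -aic / 2, aic = aic,
         reps = data.frame(rep = seq_along(repAics), lnL = -repAics / 2,
                           aic = repAics))
  }
  fits <- list(mk("A", 100, c(100, 101, 100)),
               mk("B", 101.5, c(101.5, 100.5, 102)),
               mk("C", 110, c(110, 111, 109)))
  sel <- modelSelection(fits)
  expect_equal(sel$delta, c(0, 1.5, 10))
  w <- exp(-c(0, 1.5, 10) / 2); w <- w / sum(w)
  expect_equal(sel$weight, w, tolerance = 1e-12)
  expect_equal(round(sel$weight, 3), c(0.676, 0.319, 0.005))
  expect_equal(sel$selectionFreq, c(2 / 3, 1 / 3, 0))
  expect_equal(sel$jointlySupported, c(TRUE, TRUE, FALSE))
  # equal AICs: equal weights; delta 2.9 still jointly supported
  fits2 <- list(mk("A", 100, 100), mk("B", 100, 100))
  expect_equal(modelSelection(fits2)$weight, c(0.5, 0.5))
  fits3 <- list(mk("A", 100, 100), mk("B", 102.9, 102.9))
  expect_equal(modelSelection(fits3)$jointlySupported, c(TRUE, TRUE))
})

test_that("parametric bootstrap brackets the estimate and widens with fewer SNPs", {
  mB <- demographicModel("B", nCur = 2000)
  truth <- c(nAnc = 1e4, tBot = 200)
  obsBig <- simulateSFS(mB, truth, 15, 2000, seed = 9)
  fitBig <- fitModel(obsBig, mB, nReps = 2, seed = 10)
  btBig <- parametricBootstrap(fitBig, 15, 2000, nBoot = 12, nCycles = 10,
                               seed = 11)
  ciBig <- btBig$ci[btBig$ci$param == "tBot", ]
  expect_lte(ciBig$low, ciBig$high)
  obsSmall <- simulateSFS(mB, truth, 15, 300, seed = 9)
  fitSmall <- fitModel(obsSmall, mB, nReps = 2, seed = 10)
  btSmall <- parametricBootstrap(fitSmall, 15, 300, nBoot = 12, nCycles = 10,
                                 seed = 11)
  ciSmall <- btSmall$ci[btSmall$ci$param == "tBot", ]
  expect_gt(ciSmall$high - ciSmall$low, ciBig$high - ciBig$low)
  expect_gte(btBig$nSuccess, 10)
})

test_that("generation-to-year conversion reproduces the invasion dating", {
  expect_equal(generationsToYears(114)$yearsRounded, 21)
  expect_equal(generationsToYears(217)$yearsRounded, 39)
  expect_equal(generationsToYears(55)$years, 10)
  expect_equal(generationsToYears(114)$years, 114 / 5.5)
  expect_error(generationsToYears(100, 0), "positive")
})

test_that("reduction fractions match the published severity claims", {
  expect_equal(reductionFraction(206750, 1044983), 1 - 206750 / 1044983)
  expect_gt(reductionFraction(206750, 1044983), 0.80)
  expect_gt(reductionFraction(48600, 1044710), 0.95)
  expect_equal(reductionFraction(5e4, 5e4), 0)
  expect_error(reductionFraction(1, -1), "positive")
})

test_that("observed folded SFS tabulates minor-allele classes", {
  gt <- rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(1L, 2L, 0L), c(0L, 1L, NA))
  gm <- toyGM(gt, pops = rep("p", 4))
  sfs <- observedFoldedSFS(gm)
  # site 3 dropped (missing); minor copies: site1 = 1, site2 = 1 (7 alt of 8)
  expect_equal(sfsSampleSize(sfs), 4L)
  expect_equal(sfsCounts(sfs), c(0, 2, 0, 0, 0))
  f <- tempfile()
  writeSFS(sfs, f)
  back <- readSFS(f)
  expect_equal(sfsCounts(back), sfsCounts(sfs))
  expect_equal(sfsSampleSize(back), 4L)
})
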