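test_that("heterozygosity matches hand computations with the unbiased correction", {
  gm <- toyGM(matrix(c(0L, 1L, 1L, 2L), 4, 1), pops = rep("p", 4))
  h <- heterozygosity(gm, "p")
  expect_equal(h[["Ho"]], 0.5)
  expect_equal(h[["He"]], 2 * 0.25 * 8 / 7, tolerance = 1e-12)
  # all heterozygous
  gmH <- toyGM(matrix(1L, 4, 1), pops = rep("p", 4))
  expect_equal(heterozygosity(gmH, "p")[["Ho"]], 1)
  # monomorphic site contributes He = Ho = 0
  gm0 <- toyGM(matrix(0L, 4, 1), pops = rep("p", 4))
  expect_equal(unname(heterozygosity(gm0, "p")), c(0, 0))
  expect_error(heterozygosity(gm, "nope"), "unknown population")
})

test_that("He and Ho are invariant to swapping allele labels", {
  set.seed(8)
  gt <- matrix(rbinom(12 * 80, 2, runif(80, 0.1, 0.9)), 12, 80, byrow = FALSE)
  gm <- toyGM(gt, pops = rep("p", 12))
  gmSwap <- toyGM(2L - gt, pops = rep("p", 12))
  expect_equal(heterozygosity(gm, "p"), heterozygosity(gmSwap, "p"))
})

test_that("FIS hits its endpoints and bootstrap CI brackets the estimate", {
  # all homozygotes at polymorphic sites: Fis = 1
  gt1 <- matrix(rep(c(0L, 0L, 2L, 2L), 10), 4, 10)
  f1 <- inbreedingFis(toyGM(gt1, pops = rep("p", 4)), "p", nBoot = 99)
  expect_equal(f1$fis, 1)
  # heterozygote excess: Fis < 0
  gt2 <- matrix(1L, 6, 10)
  gt2[1, ] <- 0L
  f2 <- inbreedingFis(toyGM(gt2, pops = rep("p", 6)), "p", nBoot = 499,
                      seed = 2)
  expect_lt(f2$fis, 0)
  expect_lte(f2$ciLow, f2$fis)
  expect_gte(f2$ciHigh, f2$fis)
})

test_that("rarefied allelic richness follows the hypergeometric formula", {
  # allele counts (3,1): Ar(g=2) = 1 + (1 - C(3,2)/C(4,2)) = 1.5
  gm <- toyGM(matrix(c(0L, 1L, NA, NA), 4, 1), pops = rep("p", 4))
  expect_equal(allelicRichness(gm, "p", 2)$arMean, 1.5)
  # monomorphic: Ar = 1 for any g
  gm0 <- toyGM(matrix(2L, 5, 1), pops = rep("p", 5))
  expect_equal(allelicRichness(gm0, "p", 2)$arMean, 1)
  expect_equal(allelicRichness(gm0, "p", 10)$arMean, 1)
  # g = n: observed allele count
  gm2 <- toyGM(matrix(c(0L, 1L, 1L, 2L), 4, 1), pops = rep("p", 4))
  expect_equal(allelicRichness(gm2, "p", 8)$arMean, 2)
  expect_error(allelicRichness(gm2, "p", 1), "rarefaction")
  # monotone non-decreasing in g
  ar <- vapply(2:8, function(g) allelicRichness(gm2, "p", g)$arMean,
               numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("private alleles count planted population-specific alleles", {
  # 3 pops x 4 ind; site 1: alt only in pop a; site 2: ref only in pop b;
  # site 3: everything shared
  gt <- cbind(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
              c(2L, 2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L),
              rep(1L, 12))
  gm <- toyGM(gt, pops = rep(c("a", "b", "c"), each = 4))
  pa <- privateAlleles(gm)
  expect_equal(unname(pa[c("a", "b", "c")]), c(1L, 1L, 0L))
  gmShared <- toyGM(matrix(1L, 12, 3), pops = rep(c("a", "b", "c"), each = 4))
  expect_equal(sum(privateAlleles(gmShared)), 0L)
})

test_that("nucleotide diversity equals the brute-force pairwise oracle", {
  # one variant site, p = 0.5 among 2 diploids, 100 total sites
  gm <- toyGM(matrix(c(1L, 1L), 2, 1), pops = rep("p", 2))
  expect_equal(nucleotideDiversity(gm, "p", 100),
               piPairwiseOracle(2, 4) / 100, tolerance = 1e-12)
  # multi-site: sum of per-site oracle values over total length
  set.seed(4)
  gt <- matrix(rbinom(5 * 40, 2, 0.3), 5, 40)
  gm2 <- toyGM(gt, pops = rep("p", 5))
  expected <- sum(vapply(seq_len(40), function(l)
    piPairwiseOracle(sum(gt[, l]), 10), numeric(1))) / 5000
  expect_equal(nucleotideDiversity(gm2, "p", 5000), expected,
               tolerance = 1e-12)
  expect_equal(nucleotideDiversity(toyGM(matrix(0L, 4, 1), pops = rep("p", 4)),
                                   "p", 10), 0)
  expect_error(nucleotideDiversity(gm, "p", 0), "positive")
})

test_that("effective size follows pi / 4mu", {
  expect_equal(effectiveSize(0.003, 2.8e-9), 0.003 / (4 * 2.8e-9))
  expect_equal(effectiveSize(0, 1e-8), 0)
  expect_equal(effectiveSize(4e-8, 1e-8), 1)
  expect_error(effectiveSize(0.01, 0), "mu")
})

test_that("Tajima's D is negative for an all-singleton window", {
  nInd <- 10L
  gt <- matrix(0L, nInd, 12)
  for (l in seq_len(12)) gt[(l %% nInd) + 1L, l] <- 1L
  gm <- toyGM(gt, pops = rep("p", nInd), pos = seq_len(12) * 1000L)
  td <- tajimasD(gm, "p")
  expect_equal(nrow(td$windows), 1L)
  expect_lt(td$mean, 0)
})

test_that("windowing splits sites by position and SE is across windows", {
  set.seed(9)
  gt <- matrix(rbinom(10 * 200, 2, 0.3), 10, 200)
  pos <- as.integer(seq(1, 4e7, length.out = 200))
  gm <- toyGM(gt, pops = rep("p", 10), pos = pos)
  td <- tajimasD(gm, "p", windowBp = 1e7)
  expect_equal(nrow(td$windows), 4L)
  expect_equal(sum(td$windows$nSnps), 200L)
  d <- td$windows$D
  expect_equal(td$se, sd(d) / sqrt(length(d)))
})

test_that("diversity summary assembles one row per population", {
  set.seed(10)
  gt <- matrix(rbinom(12 * 60, 2, 0.4), 12, 60)
  gm <- toyGM(gt, pops = rep(c("a", "b"), each = 6),
              pos = as.integer(seq(1, 3e7, length.out = 60)))
  tab <- diversitySummary(gm, nBoot = 99)
  expect_equal(tab$pop, c("a", "b"))
  expect_true(all(tab$He >= 0 & tab$He <= 1))
  expect_true(all(tab$Ho >= 0 & tab$Ho <= 1))
  expect_true(all(tab$Fis >= -1 & tab$Fis <= 1))
  expect_true(all(tab$privateAlleles >= 0))
})
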