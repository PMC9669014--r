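test_that("rank-1 genotype structure loads entirely on PC1", {
  gt <- rbind(matrix(0L, 5, 30), matrix(2L, 5, 30))
  gm <- toyGM(gt, pops = rep(c("a", "b"), each = 5))
  p <- pcaGenotypes(gm)
  expect_equal(p$varExplained[1], 1, tolerance = 1e-10)
})

test_that("duplicated individuals get identical PCA coordinates", {
  set.seed(15)
  gt <- matrix(rbinom(6 * 50, 2, 0.4), 6, 50)
  gt <- rbind(gt, gt[3, ])
  gm <- toyGM(gt, pops = rep("p", 7))
  p <- pcaGenotypes(gm)
  expect_equal(unname(p$coords[3, ]), unname(p$coords[7, ]),
               tolerance = 1e-8)
})

test_that("PCA scores equal the SVD oracle up to sign", {
  set.seed(16)
  gt <- matrix(rbinom(10 * 80, 2, 0.3), 10, 80)
  gt[sample(length(gt), 40)] <- NA
  gm <- toyGM(gt, pops = rep("p", 10))
  p <- pcaGenotypes(gm, nComponents = 4)
  # independent route: mean-impute, center, svd
  X <- gt
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  oracle <- sv$u[, 1:4] %*% diag(sv$d[1:4])
  for (k in 1:4) {
    s <- sign(sum(p$coords[, k] * oracle[, k]))
    expect_equal(unname(p$coords[, k]), s * oracle[, k], tolerance = 1e-8)
  }
  expect_true(all(diff(p$varExplained) <= 1e-12))
  expect_lte(sum(p$varExplained), 1 + 1e-8)
})

test_that("PCA ignores monomorphic columns appended after filtering", {
  set.seed(17)
  gt <- matrix(rbinom(8 * 40, 2, 0.4), 8, 40)
  gm <- toyGM(gt, pops = rep("p", 8))
  gm2 <- toyGM(cbind(gt, rep(1L, 8)), pops = rep("p", 8))
  p1 <- pcaGenotypes(gm, nComponents = 3)
  p2 <- pcaGenotypes(gm2, nComponents = 3)
  expect_equal(abs(p1$coords), abs(p2$coords), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("K = 1 gives unit ancestry and rows always sum to one", {
  set.seed(18)
  gt <- matrix(rbinom(8 * 60, 2, 0.4), 8, 60)
  gm <- toyGM(gt, pops = rep("p", 8))
  a1 <- admixtureQ(gm, K = 1, nRuns = 2, seed = 1)
  expect_equal(unname(a1$Q[, 1]), rep(1, 8))
  a3 <- admixtureQ(gm, K = 3, nRuns = 2, seed = 1)
  expect_lt(max(abs(rowSums(a3$Q) - 1)), 1e-6)
  expect_true(all(a3$Q >= 0 & a3$Q <= 1))
})

test_that("permuting individuals permutes Q rows identically", {
  set.seed(19)
  gt <- matrix(rbinom(10 * 50, 2, 0.5), 10, 50)
  gm <- toyGM(gt, pops = rep("p", 10))
  perm <- sample(10)
  a <- admixtureQ(gm, K = 2, nRuns = 1, maxIter = 500, seed = 4)
  aP <- admixtureQ(gm[, perm], K = 2, nRuns = 1, maxIter = 500, seed = 4)
  expect_equal(unname(aP$Q), unname(a$Q[perm, ]), tolerance = 1e-10)
})

test_that("fit loss decreases monotonically across alternating updates", {
  set.seed(20)
  gt <- matrix(rbinom(12 * 80, 2, 0.4), 12, 80)
  gt[sample(length(gt), 60)] <- NA
  a <- admixtureQ(toyGM(gt, pops = rep("p", 12)), K = 2, nRuns = 1, seed = 2)
  expect_true(all(diff(a$loss) <= 1e-8))
})

test_that("strong divergence yields assignable ancestry and K = 2 wins", {
  g <- simGenotypes(simConfig("two_deme_island", nIndividuals = 12,
                              nSnps = 300, fst = 0.4, missingness = 0.02,
                              seed = 3))
  ad <- admixtureQ(g$gm, K = 2, nRuns = 3, seed = 1)
  expect_gt(mean(apply(ad$Q, 1, max)), 0.9)
  sk <- selectK(g$gm, KRange = 1:3, nReps = 3, seed = 2)
  ce <- sk$table
  expect_lt(ce$meanCE[ce$K == 2], ce$meanCE[ce$K == 1])
  expect_true(all(ce$meanCE >= 0))
})

test_that("a panmictic sample prefers K = 1 by cross-entropy", {
  g <- simGenotypes(simConfig("panmictic", nIndividuals = 15, nSnps = 300,
                              missingness = 0.02, seed = 4))
  sk <- selectK(g$gm, KRange = 1:3, nReps = 3, seed = 2)
  expect_equal(sk$bestK, 1L)
})
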