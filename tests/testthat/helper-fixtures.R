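# small builders and independent oracles used across the test files

toyGM <- function(gt, pops, pos = NULL, chrom = "chr1", depth = NULL,
                  nAlleles = NULL) {
  gt <- as.matrix(gt)
  if (is.null(pos)) pos <- seq_len(ncol(gt)) * 100L
  GenotypeMatrix(gt, chrom = chrom, pos = pos, popLabels = pops,
                 depth = depth, nAlleles = nAlleles)
}

# folded neutral SFS proportions under constant size: 1/i + 1/(2n - i),
# halved (single term) at i = n
foldedNeutralExpectation <- function(n) {
  K <- 2L * n
  i <- seq_len(n)
  f <- ifelse(i < K - i, 1 / i + 1 / (K - i), 1 / i)
  f / sum(f)
}

# literal scalar transcription of the Weir & Cockerham (1984) two-allele
# variance components, looped over loci and populations: the independent
# oracle for the vectorized estimator
wcThetaOracle <- function(gm) {
  pops <- unique(popLabels(gm))
  r <- length(pops)
  gt <- genotypes(gm)
  sumA <- 0; sumAll <- 0
  for (l in seq_len(ncol(gt))) {
    n <- p <- h <- numeric(r)
    for (j in seq_len(r)) {
      g <- gt[popLabels(gm) == pops[j], l]
      g <- g[!is.na(g)]
      n[j] <- length(g)
      if (n[j] > 0) {
        p[j] <- sum(g) / (2 * n[j])
        h[j] <- mean(g == 1)
      }
    }
    if (any(n < 2)) next
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (nc > 0 && is.finite(a + b + cc)) {
      sumA <- sumA + a
      sumAll <- sumAll + a + b + cc
    }
  }
  sumA / sumAll
}

# brute-force per-site mean pairwise difference over gene copies
piPairwiseOracle <- function(altCopies, totalCopies) {
  diffPairs <- altCopies * (totalCopies - altCopies)
  diffPairs / choose(totalCopies, 2)
}

# folded SFS counts from msprime (branch-mode AFS summed over replicate
# genealogies = length-biased expectation, then one multinomial draw)
msprimeFoldedCounts <- function(nDip, Ne, nSnps, nRep = 4000, seed = 1) {
  script <- sprintf(
    "import msprime, numpy as np
tot = None
for ts in msprime.sim_ancestry(samples=%d, ploidy=2, population_size=%g,
                               num_replicates=%d, random_seed=%d):
    a = ts.allele_frequency_spectrum(mode='branch', polarised=False,
                                     span_normalise=False)
    tot = a if tot is None else tot + a
p = tot[1:%d] / tot[1:%d].sum()
rng = np.random.default_rng(%d)
cnt = rng.multinomial(%d, p)
print(' '.join(str(int(x)) for x in cnt))
", nDip, Ne, nRep, seed, nDip + 1, nDip + 1, seed, nSnps)
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  as.numeric(strsplit(tail(out, 1), " ")[[1]])
}
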