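# Weir & Cockerham (1984) per-locus variance components a, b, c for a
# biallelic locus across r populations. gtList: one genotype matrix per pop.
wcComponents <- function(gtList) {
  r <- length(gtList)
  nMat <- vapply(gtList, function(g) colSums(!is.na(g)), numeric(ncol(gtList[[1]])))
  pMat <- vapply(gtList, altFreq, numeric(ncol(gtList[[1]])))
  hMat <- vapply(gtList, function(g)
    colSums(g == 1L, na.rm = TRUE) / pmax(colSums(!is.na(g)), 1L),
    numeric(ncol(gtList[[1]])))
  use <- rowSums(nMat >= 2L) == r
  nMat <- nMat[use, , drop = FALSE]
  pMat <- pMat[use, , drop = FALSE]
  hMat <- hMat[use, , drop = FALSE]

  nbar <- rowMeans(nMat)
  nc <- (r * nbar - rowSums(nMat^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(nMat * pMat) / (r * nbar)
  s2 <- rowSums(nMat * (pMat - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nMat * hMat) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  ok <- nc > 0 & is.finite(a) & is.finite(b) & is.finite(c)
  list(a = a[ok], b = b[ok], c = c[ok], nLoci = sum(ok))
}

# multilocus theta = sum(a) / sum(a + b + c)
wcTheta <- function(comp) {
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) stop("Weir-Cockerham theta undefined: zero total variance")
  sum(comp$a) / denom
}

#' Pairwise Weir-Cockerham FST with bootstrap intervals
#'
#' Multilocus theta between every pair of populations: the ratio of summed
#' among-population variance components to summed total components over loci
#' (Weir & Cockerham's estimator), with a percentile bootstrap over loci for
#' confidence intervals. Loci need at least two genotyped individuals in each
#' population of the pair; slightly negative estimates are possible and are
#' not truncated.
#'
#' @param gm a [GenotypeMatrix-class] with at least two populations of at
#'   least two individuals each.
#' @param nBoot bootstrap replicates over loci (default 9999; 0 disables
#'   intervals).
#' @param alpha two-sided interval level.
#' @param seed RNG seed for the resampling.
#' @return List with `pops`, the symmetric matrix `theta` (diagonal 0), and
#'   matrices `ciLow` / `ciHigh` when `nBoot > 0`.
#' @export
pairwiseFst <- function(gm, nBoot = 9999, alpha = 0.05, seed = 1L) {
  pops <- unique(popLabels(gm))
  if (length(pops) < 2L) stop("pairwise FST needs at least 2 populations")
  if (any(table(popLabels(gm)) < 2L))
    stop("each population needs at least 2 individuals")
  k <- length(pops)
  theta <- matrix(0, k, k, dimnames = list(pops, pops))
  ciLow <- ciHigh <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  seeds <- subSeeds(seed, k * k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    comp <- wcComponents(list(popGenotypes(gm, pops[i]),
                              popGenotypes(gm, pops[j])))
    th <- wcTheta(comp)
    theta[i, j] <- theta[j, i] <- th
    if (nBoot > 0) {
      L <- comp$nLoci
      abc <- comp$a + comp$b + comp$c
      boot <- withSeed(seeds[(i - 1) * k + j], vapply(seq_len(nBoot),
        function(b) {
          idx <- sample.int(L, L, replace = TRUE)
          den <- sum(abc[idx])
          if (den == 0) NA_real_ else sum(comp$a[idx]) / den
        }, numeric(1)))
      q <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                           names = FALSE)
      ciLow[i, j] <- ciLow[j, i] <- q[1]
      ciHigh[i, j] <- ciHigh[j, i] <- q[2]
    }
  }
  out <- list(pops = pops, theta = theta)
  if (nBoot > 0) {
    out$ciLow <- ciLow
    out$ciHigh <- ciHigh
  }
  out
}
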