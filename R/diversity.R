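popGenotypes <- function(gm, pop) {
  sel <- popLabels(gm) == pop
  if (!any(sel)) stop("unknown population: ", pop)
  genotypes(gm)[sel, , drop = FALSE]
}

# per-site observed het, Nei-unbiased expected het, and non-missing n
siteHet <- function(gt) {
  nn <- colSums(!is.na(gt))
  p <- altFreq(gt)
  ho <- colSums(gt == 1L, na.rm = TRUE) / pmax(nn, 1L)
  he <- 2 * p * (1 - p) * (2 * nn) / pmax(2 * nn - 1, 1)
  use <- nn >= 2L
  list(ho = ho, he = he, n = nn, use = use)
}

#' Expected and observed heterozygosity for one population
#'
#' Per site, observed heterozygosity is the fraction of heterozygotes among
#' non-missing genotypes and expected heterozygosity is the Nei unbiased
#' estimate `2p(1-p) * 2n/(2n-1)` with `n` the number of genotyped diploids
#' at the site. Population values are means over sites with at least two
#' genotyped individuals.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label.
#' @return Named numeric vector `c(He = ..., Ho = ...)`.
#' @export
heterozygosity <- function(gm, pop) {
  h <- siteHet(popGenotypes(gm, pop))
  c(He = mean(h$he[h$use]), Ho = mean(h$ho[h$use]))
}

#' Multilocus inbreeding coefficient with bootstrap interval
#'
#' FIS is computed as `1 - mean(Ho) / mean(He)` over sites (ratio of
#' averages); the confidence interval is a percentile bootstrap over sites.
#' Negative values indicate heterozygote excess relative to Hardy-Weinberg
#' expectation, the signature expected shortly after a strong founder event.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label.
#' @param nBoot bootstrap replicates (default 9999).
#' @param alpha two-sided interval level (default 0.05 for a 95% CI).
#' @param seed RNG seed for the resampling.
#' @return List with `fis`, `ciLow`, `ciHigh`, `nBoot`.
#' @export
inbreedingFis <- function(gm, pop, nBoot = 9999, alpha = 0.05, seed = 1L) {
  h <- siteHet(popGenotypes(gm, pop))
  ho <- h$ho[h$use]; he <- h$he[h$use]
  poly <- he > 0
  if (sum(poly) < 2L) stop("need at least 2 polymorphic sites for FIS")
  if (mean(he) == 0) stop("FIS undefined: He is zero over all sites")
  fis <- 1 - mean(ho) / mean(he)
  L <- length(ho)
  boot <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
    idx <- sample.int(L, L, replace = TRUE)
    heB <- mean(he[idx])
    if (heB == 0) return(NA_real_)
    1 - mean(ho[idx]) / heB
  }, numeric(1)))
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(fis = fis, ciLow = ci[1], ciHigh = ci[2], nBoot = nBoot)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a standardized subsample of `g`
#' gene copies, computed per site by the hypergeometric rarefaction formula
#' `sum_a [1 - C(n - n_a, g) / C(n, g)]` with `n` the non-missing gene copies
#' and `n_a` the copies of allele `a`, then averaged over sites (per-locus
#' mean). The per-dataset sum is also returned.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label.
#' @param g rarefaction size in gene copies (must be >= 2); sites with fewer
#'   than `g` non-missing copies are skipped.
#' @return List with `arMean` (per-locus mean), `arSum` (sum over sites) and
#'   `nSitesUsed`.
#' @export
allelicRichness <- function(gm, pop, g) {
  if (g < 2) stop("invalid rarefaction size: g must be >= 2")
  gt <- popGenotypes(gm, pop)
  nn <- colSums(!is.na(gt))
  n <- 2 * nn
  cAlt <- colSums(gt, na.rm = TRUE)
  use <- n >= g
  if (!any(use)) stop("no site has at least g = ", g, " gene copies")
  rar <- function(n, na, g) {
    # P(allele absent from subsample) = C(n - na, g) / C(n, g)
    out <- numeric(length(n))
    ok <- na > 0
    pAbsent <- ifelse(n - na >= g, exp(lchoose(n - na, g) - lchoose(n, g)), 0)
    out[ok] <- 1 - pAbsent[ok]
    out
  }
  arSite <- rar(n[use], cAlt[use], g) + rar(n[use], n[use] - cAlt[use], g)
  list(arMean = mean(arSite), arSum = sum(arSite), nSitesUsed = sum(use))
}

#' Private alleles per population
#'
#' Counts (site, allele) pairs in which the allele is observed in exactly one
#' population.
#'
#' @param gm a [GenotypeMatrix-class] with at least two populations.
#' @return Named integer vector of private-allele counts per population.
#' @export
privateAlleles <- function(gm) {
  pops <- unique(popLabels(gm))
  if (length(pops) < 2L) stop("private alleles need at least 2 populations")
  gt <- genotypes(gm)
  hasRef <- vapply(pops, function(p) {
    g <- gt[popLabels(gm) == p, , drop = FALSE]
    colSums(g < 2L, na.rm = TRUE) > 0L
  }, logical(ncol(gt)))
  hasAlt <- vapply(pops, function(p) {
    g <- gt[popLabels(gm) == p, , drop = FALSE]
    colSums(g > 0L, na.rm = TRUE) > 0L
  }, logical(ncol(gt)))
  count <- function(hasMat) {
    privateIn <- rowSums(hasMat) == 1L
    colSums(hasMat & privateIn)
  }
  out <- count(hasRef) + count(hasAlt)
  stats::setNames(as.integer(out), pops)
}

#' Nucleotide diversity per sequenced site
#'
#' Mean pairwise difference per site, using variant and invariant sites: the
#' per-site unbiased heterozygosity `2p(1-p) * 2n/(2n-1)` summed over variant
#' sites and divided by the total number of sequenced sites (variant +
#' invariant).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label.
#' @param totalSites total sequenced sites including invariant ones; must be
#'   at least the number of variant sites.
#' @return Per-site nucleotide diversity (dimensionless).
#' @export
nucleotideDiversity <- function(gm, pop, totalSites) {
  if (totalSites <= 0) stop("totalSites must be positive")
  if (totalSites < nSites(gm))
    stop("totalSites must be >= the number of variant sites")
  h <- siteHet(popGenotypes(gm, pop))
  sum(h$he[h$use]) / totalSites
}

#' Long-term effective population size from diversity
#'
#' Under neutral mutation-drift equilibrium, `Ne = pi / (4 mu)` for a diploid
#' population with per-site nucleotide diversity `pi` and per-site,
#' per-generation mutation rate `mu`.
#'
#' @param pi per-site nucleotide diversity.
#' @param mu mutation rate per site per generation.
#' @return Diploid effective population size.
#' @examples
#' effectiveSize(0.003, 2.8e-9)  # ~268k
#' @export
effectiveSize <- function(pi, mu) {
  if (mu <= 0) stop("mu must be positive")
  pi / (4 * mu)
}

#' Windowed Tajima's D
#'
#' The standardized difference between mean pairwise diversity and
#' Watterson's theta, computed in non-overlapping windows of `windowBp` base
#' pairs along each chromosome with the canonical a1, a2, b1, b2, c1, c2, e1,
#' e2 constants at `m = 2 x` (individuals in the population) gene copies.
#' Negative values signal an excess of low-frequency variants as produced by
#' population expansion after a bottleneck. Per-site diversity uses the
#' non-missing gene copies at each site; the constants use the nominal sample
#' size.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label.
#' @param windowBp window length in base pairs (default 1e7, i.e. 10 Mbp).
#' @return List with `windows` (data.frame: chrom, start, end, nSnps, S, pi,
#'   D), `mean` and `se` of D across windows with a defined value.
#' @export
tajimasD <- function(gm, pop, windowBp = 1e7) {
  gt <- popGenotypes(gm, pop)
  m <- 2L * nrow(gt)
  if (m < 4L) stop("Tajima's D needs at least 2 diploid individuals")
  i <- seq_len(m - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)

  nn <- colSums(!is.na(gt))
  p <- altFreq(gt)
  seg <- !is.na(p) & p > 0 & p < 1 & nn >= 2L
  piSite <- ifelse(seg, 2 * p * (1 - p) * (2 * nn) / pmax(2 * nn - 1, 1), 0)

  chrom <- siteChrom(gm); pos <- sitePos(gm)
  win <- paste(chrom, (pos - 1L) %/% windowBp)
  rows <- lapply(split(seq_along(win), win), function(idx) {
    S <- sum(seg[idx])
    piW <- sum(piSite[idx])
    D <- if (S >= 1) {
      denom <- sqrt(e1 * S + e2 * S * (S - 1))
      if (denom > 0) (piW - S / a1) / denom else NA_real_
    } else NA_real_
    data.frame(chrom = chrom[idx[1]],
               start = ((pos[idx[1]] - 1L) %/% windowBp) * windowBp + 1,
               nSnps = length(idx), S = S, pi = piW, D = D)
  })
  tab <- do.call(rbind, rows)
  tab$end <- tab$start + windowBp - 1
  tab <- tab[order(tab$chrom, tab$start),
             c("chrom", "start", "end", "nSnps", "S", "pi", "D")]
  rownames(tab) <- NULL
  d <- tab$D[!is.na(tab$D)]
  if (!length(d)) {
    warning("no polymorphic window; Tajima's D undefined")
    return(list(windows = tab, mean = NA_real_, se = NA_real_))
  }
  list(windows = tab, mean = mean(d),
       se = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_)
}

#' Per-population diversity summary table
#'
#' Convenience wrapper assembling, per population: sample size, expected and
#' observed heterozygosity, rarefied allelic richness, FIS with bootstrap CI,
#' mean windowed Tajima's D with its standard error, and private alleles.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param g rarefaction size in gene copies; defaults to twice the smallest
#'   population sample size.
#' @param nBoot bootstrap replicates for the FIS interval.
#' @param windowBp Tajima's D window size in bp.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per population.
#' @export
diversitySummary <- function(gm, g = NULL, nBoot = 9999, windowBp = 1e7,
                             seed = 1L) {
  pops <- unique(popLabels(gm))
  if (is.null(g)) g <- 2L * min(table(popLabels(gm)))
  pa <- if (length(pops) > 1L) privateAlleles(gm) else
    stats::setNames(rep(NA_integer_, length(pops)), pops)
  rows <- lapply(pops, function(p) {
    het <- heterozygosity(gm, p)
    fis <- inbreedingFis(gm, p, nBoot = nBoot, seed = seed)
    ar <- allelicRichness(gm, p, g = g)
    td <- tajimasD(gm, p, windowBp = windowBp)
    data.frame(pop = p, n = sum(popLabels(gm) == p),
               He = het[["He"]], Ho = het[["Ho"]],
               Ar = ar$arMean, ArSum = ar$arSum,
               Fis = fis$fis, FisLow = fis$ciLow, FisHigh = fis$ciHigh,
               TajimaD = td$mean, TajimaDse = td$se,
               privateAlleles = pa[[p]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
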