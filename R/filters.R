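siteIds <- function(gm) paste(siteChrom(gm), sitePos(gm), sep = ":")

# alternate-allele frequency per site, pairwise-complete over individuals
altFreq <- function(gt) {
  nn <- colSums(!is.na(gt))
  cnt <- colSums(gt, na.rm = TRUE)
  ifelse(nn > 0, cnt / (2 * nn), NA_real_)
}

#' Apply per-site filters in a fixed order
#'
#' Sites are removed sequentially under the criteria (1) allele number, (2)
#' site missingness, (3) mean read depth (only when depth is available), (4)
#' monomorphic, (5) minor allele frequency, (6) external exclusion list (the
#' plug point for outlier-SNP scans). Removal counts are reported per
#' criterion in that order, so they sum to the total number of sites lost.
#'
#' Frequencies are computed pairwise-complete (missing genotypes ignored).
#' A site survives missingness when its missing fraction is strictly below
#' `maxSiteMissing`, and the MAF filter when its minor allele frequency is at
#' least `mafMin`; set `mafMin = NA` in the [FilterSpec()] to keep rare
#' variants for demographic inference.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param spec a [FilterSpec-class].
#' @param verbose emit one `FILTER <criterion> removed=<n>` message per step.
#' @return A list with elements `gm` (the filtered [GenotypeMatrix-class])
#'   and `removed`, a named integer vector of per-criterion removal counts.
#' @export
filterSites <- function(gm, spec = FilterSpec(), verbose = FALSE) {
  stopifnot(nSites(gm) > 0L)
  keep <- rep(TRUE, nSites(gm))
  removed <- c(alleles = 0L, missingness = 0L, depth = 0L, monomorphic = 0L,
               maf = 0L, excluded = 0L)
  gt <- genotypes(gm)

  drop <- keep & siteNAlleles(gm) > spec@maxAlleles
  removed["alleles"] <- sum(drop); keep <- keep & !drop

  missFrac <- colMeans(is.na(gt))
  drop <- keep & missFrac >= spec@maxSiteMissing
  removed["missingness"] <- sum(drop); keep <- keep & !drop

  d <- siteDepth(gm)
  drop <- keep & !is.na(d) & (d < spec@depthMin | d > spec@depthMax)
  removed["depth"] <- sum(drop); keep <- keep & !drop

  p <- altFreq(gt)
  drop <- keep & (is.na(p) | p == 0 | p == 1)
  removed["monomorphic"] <- sum(drop); keep <- keep & !drop

  if (!is.na(spec@mafMin)) {
    maf <- pmin(p, 1 - p)
    drop <- keep & maf < spec@mafMin
    removed["maf"] <- sum(drop); keep <- keep & !drop
  }

  if (length(spec@excludeSites)) {
    drop <- keep & siteIds(gm) %in% spec@excludeSites
    removed["excluded"] <- sum(drop); keep <- keep & !drop
  }

  if (verbose)
    for (k in names(removed))
      message(sprintf("FILTER %s removed=%d", k, removed[[k]]))
  if (!any(keep))
    warning("all sites removed by filters; result is empty")
  list(gm = gm[keep, ], removed = removed)
}

#' Remove individuals with excessive missing data
#'
#' @param gm a [GenotypeMatrix-class].
#' @param maxMissing individuals with a missing-genotype fraction strictly
#'   greater than this are dropped (default 0.45). Survivor order is
#'   preserved.
#' @param verbose emit a `FILTER individuals removed=<n>` message.
#' @return The filtered [GenotypeMatrix-class].
#' @export
filterIndividuals <- function(gm, maxMissing = 0.45, verbose = FALSE) {
  stopifnot(maxMissing >= 0, maxMissing <= 1)
  missFrac <- rowMeans(is.na(genotypes(gm)))
  keep <- missFrac <= maxMissing
  if (verbose)
    message(sprintf("FILTER individuals removed=%d", sum(!keep)))
  gm[, keep]
}

#' Prune sites in linkage disequilibrium
#'
#' Sliding windows of `window` sites shifted by `step` sites within each
#' chromosome; within a window, for every pair of still-retained sites whose
#' pairwise genotype correlation exceeds the r-squared equivalent of the VIF
#' threshold (r2 > 1 - 1/VIF, so VIF 2 maps to r2 > 0.5), the later site in
#' input order is removed. The procedure is deterministic given site order,
#' and the output contains no within-window pair above the threshold.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param window,step window size and shift, counted in sites.
#' @param vif variance inflation factor threshold.
#' @param verbose emit a `FILTER ld removed=<n>` message.
#' @return The pruned [GenotypeMatrix-class].
#' @export
ldPrune <- function(gm, window = 50L, step = 5L, vif = 2, verbose = FALSE) {
  stopifnot(window >= 2L, step >= 1L, step <= window, vif > 1)
  r2max <- 1 - 1 / vif
  gt <- genotypes(gm)
  keep <- rep(TRUE, nSites(gm))
  chrom <- siteChrom(gm)
  for (ch in unique(chrom)) {
    idxAll <- which(chrom == ch)
    starts <- seq(1L, max(1L, length(idxAll) - 1L), by = step)
    for (s in starts) {
      win <- idxAll[s:min(s + window - 1L, length(idxAll))]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      cc <- suppressWarnings(stats::cor(gt[, win, drop = FALSE],
                                        use = "pairwise.complete.obs"))
      r2 <- cc^2
      for (j in 2:length(win)) {
        if (!keep[win[j]]) next
        for (i in 1:(j - 1)) {
          if (keep[win[i]] && !is.na(r2[i, j]) && r2[i, j] > r2max) {
            keep[win[j]] <- FALSE
            break
          }
        }
      }
    }
  }
  if (verbose) message(sprintf("FILTER ld removed=%d", sum(!keep)))
  gm[keep, ]
}
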