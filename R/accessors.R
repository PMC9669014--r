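#' @describeIn GenotypeMatrix-class genotype matrix, individuals x sites,
#'   alternate-allele counts with `NA` for missing.
#' @param gm a [GenotypeMatrix-class].
#' @export
genotypes <- function(gm) t(SummarizedExperiment::assay(gm, "GT"))

#' @describeIn GenotypeMatrix-class population label per individual.
#' @export
popLabels <- function(gm) SummarizedExperiment::colData(gm)$pop

#' @describeIn GenotypeMatrix-class chromosome/scaffold per site.
#' @export
siteChrom <- function(gm) SummarizedExperiment::rowData(gm)$chrom

#' @describeIn GenotypeMatrix-class 1-based position per site.
#' @export
sitePos <- function(gm) SummarizedExperiment::rowData(gm)$pos

#' @describeIn GenotypeMatrix-class mean read depth per site (NA if absent).
#' @export
siteDepth <- function(gm) SummarizedExperiment::rowData(gm)$depth

#' @describeIn GenotypeMatrix-class allele number per site from the VCF.
#' @export
siteNAlleles <- function(gm) SummarizedExperiment::rowData(gm)$nAlleles

#' @describeIn GenotypeMatrix-class individual identifiers.
#' @export
individualIds <- function(gm) colnames(SummarizedExperiment::assay(gm, "GT"))

#' @describeIn GenotypeMatrix-class number of individuals.
#' @export
nIndividuals <- function(gm) ncol(SummarizedExperiment::assay(gm, "GT"))

#' @describeIn GenotypeMatrix-class number of sites.
#' @export
nSites <- function(gm) nrow(SummarizedExperiment::assay(gm, "GT"))

#' Subset a GenotypeMatrix by individuals and/or sites
#'
#' @param gm a [GenotypeMatrix-class].
#' @param individuals logical/integer/character index over individuals.
#' @param sites logical/integer index over sites.
#' @return A [GenotypeMatrix-class] restricted to the selection.
#' @export
subsetGenotypes <- function(gm, individuals = NULL, sites = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nIndividuals(gm))
  if (is.null(sites)) sites <- seq_len(nSites(gm))
  gm[sites, individuals]
}

#' @describeIn FoldedSFS-class SNP counts per minor-allele copy class
#'   (index 0 .. n).
#' @param sfs a [FoldedSFS-class].
#' @export
sfsCounts <- function(sfs) sfs@counts

#' @describeIn FoldedSFS-class diploid sample size.
#' @export
sfsSampleSize <- function(sfs) sfs@nIndividuals

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d sites\n",
              nIndividuals(object), nSites(object)))
  gt <- SummarizedExperiment::assay(object, "GT")
  miss <- mean(is.na(gt))
  pops <- table(popLabels(object))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  cat("  populations: ",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat(sprintf("  chromosomes: %d\n", length(unique(siteChrom(object)))))
})

setMethod("show", "FoldedSFS", function(object) {
  nPoly <- sum(object@counts[-1])
  cat(sprintf("FoldedSFS: n = %d diploids (2n = %d gene copies), %d SNPs\n",
              object@nIndividuals, 2L * object@nIndividuals, round(nPoly)))
  cat("  counts:", paste(round(object@counts), collapse = " "), "\n")
})

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel %s (N_CUR = %s, fixed)\n", object@modelId,
              format(object@nCur, big.mark = ",")))
  fp <- freeParams(object)
  if (!length(fp)) {
    cat("  no free parameters (constant-size null model)\n")
  } else {
    for (p in fp) {
      b <- object@bounds[[p]]
      cat(sprintf("  %-8s in [%g, %g]\n", p, b[1], b[2]))
    }
  }
})

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec:\n")
  cat(sprintf("  maxAlleles=%d  maxSiteMissing=%g  depth=[%g,%g]\n",
              object@maxAlleles, object@maxSiteMissing,
              object@depthMin, object@depthMax))
  cat(sprintf("  maxIndivMissing=%g  mafMin=%s\n", object@maxIndivMissing,
              ifelse(is.na(object@mafMin), "disabled", object@mafMin)))
  cat(sprintf("  LD: window=%d step=%d VIF=%g (r2 > %g)  excludeSites: %d\n",
              object@ldWindow, object@ldStep, object@ldVif,
              1 - 1 / object@ldVif, length(object@excludeSites)))
})
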