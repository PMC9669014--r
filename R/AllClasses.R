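#' @import methods
#' @import stats
#' @importFrom utils head tail
#' @useDynLib invagen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

GT_CODES <- c(0L, 1L, 2L)

#' Diploid SNP genotype matrix
#'
#' An S4 container for diploid biallelic genotype calls, built on
#' [SummarizedExperiment::SummarizedExperiment]. The `"GT"` assay holds one
#' row per site and one column per individual, coded as the count of the
#' alternate allele (0, 1, 2) with `NA` marking missing calls. Site
#' coordinates (`chrom`, `pos`, optional mean read `depth`, and the number of
#' alleles observed in the source VCF) live in `rowData`; population labels
#' live in `colData`.
#'
#' User code should use the accessors ([genotypes()], [popLabels()],
#' [siteChrom()], [sitePos()], [siteDepth()], [individualIds()],
#' [nIndividuals()], [nSites()]) rather than reaching into slots; note that
#' [genotypes()] returns the matrix in the individuals-by-sites orientation
#' used throughout the package.
#'
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- character()
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- SummarizedExperiment::assay(object, "GT")
    bad <- gt[!is.na(gt)]
    if (length(bad) && !all(bad %in% GT_CODES))
      msg <- c(msg, "genotype values must be in {0, 1, 2, NA}")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
  else {
    for (ch in unique(rd$chrom)) {
      p <- rd$pos[rd$chrom == ch]
      if (length(p) > 1 && any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("site positions not strictly increasing on '%s'", ch))
        break
      }
    }
  }
  if (!"pop" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'pop'")
  if (length(msg)) msg else TRUE
}

setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param genotypes integer matrix, individuals in rows and sites in columns;
#'   entries are alternate-allele counts 0/1/2 or `NA` for missing.
#' @param chrom character vector of site chromosome/scaffold identifiers.
#' @param pos integer vector of 1-based site positions, strictly increasing
#'   within each chromosome.
#' @param popLabels population assignment per individual.
#' @param individualIds individual labels; defaults to rownames or `ind1..n`.
#' @param depth optional numeric vector of per-site mean read depth.
#' @param nAlleles optional integer vector of allele numbers per site as seen
#'   in the source VCF (used by the biallelic filter); defaults to 2.
#'
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 0L, 0L, 1L), nrow = 3),
#'                      chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                      popLabels = c("A", "A", "B"))
#' nSites(gm)
#' @export
GenotypeMatrix <- function(genotypes, chrom, pos, popLabels,
                           individualIds = NULL, depth = NULL,
                           nAlleles = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  nInd <- nrow(genotypes)
  nSit <- ncol(genotypes)
  if (is.null(individualIds))
    individualIds <- rownames(genotypes)
  if (is.null(individualIds))
    individualIds <- paste0("ind", seq_len(nInd))
  if (length(chrom) == 1L) chrom <- rep(chrom, nSit)
  stopifnot(length(chrom) == nSit, length(pos) == nSit,
            length(popLabels) == nInd, length(individualIds) == nInd)
  rd <- S4Vectors::DataFrame(chrom = as.character(chrom),
                             pos = as.integer(pos))
  rd$depth <- if (is.null(depth)) rep(NA_real_, nSit) else as.numeric(depth)
  rd$nAlleles <- if (is.null(nAlleles)) rep(2L, nSit) else as.integer(nAlleles)
  cd <- S4Vectors::DataFrame(pop = as.character(popLabels),
                             row.names = individualIds)
  gt <- t(genotypes)
  rownames(gt) <- paste(chrom, pos, sep = ":")
  colnames(gt) <- individualIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = gt), rowData = rd, colData = cd)
  new("GenotypeMatrix", se)
}

#' Per-site and individual filter thresholds
#'
#' Holds the thresholds used by [filterSites()], [filterIndividuals()] and
#' [ldPrune()]. Defaults follow a standard RAD-seq processing protocol:
#' biallelic sites only, site missingness below 25%, mean site depth between
#' 6X and 100X, individuals with more than 45% missing genotypes dropped,
#' minor allele frequency at least 0.03 (set `mafMin = NA` to keep rare
#' variants, as demographic inference requires), and LD pruning in sliding
#' windows of 50 sites shifted by 5 with a VIF threshold of 2.
#'
#' @slot maxAlleles maximum number of alleles per retained site.
#' @slot maxSiteMissing maximum fraction of missing genotypes per site.
#' @slot depthMin,depthMax admissible mean read depth per site (X coverage).
#' @slot maxIndivMissing maximum fraction of missing genotypes per individual.
#' @slot mafMin minimum minor allele frequency; `NA` disables the filter.
#' @slot ldWindow,ldStep sliding-window size and shift, counted in sites.
#' @slot ldVif variance inflation factor threshold; mapped to the pairwise
#'   criterion r-squared > 1 - 1/VIF.
#' @slot excludeSites site identifiers ("chrom:pos") to drop unconditionally,
#'   e.g. an externally produced outlier-SNP list.
#' @export
setClass("FilterSpec",
  representation(maxAlleles = "integer", maxSiteMissing = "numeric",
                 depthMin = "numeric", depthMax = "numeric",
                 maxIndivMissing = "numeric", mafMin = "numeric",
                 ldWindow = "integer", ldStep = "integer", ldVif = "numeric",
                 excludeSites = "character"),
  prototype(maxAlleles = 2L, maxSiteMissing = 0.25, depthMin = 6,
            depthMax = 100, maxIndivMissing = 0.45, mafMin = 0.03,
            ldWindow = 50L, ldStep = 5L, ldVif = 2, excludeSites = character()))

setValidity("FilterSpec", function(object) {
  msg <- character()
  fr <- c(object@maxSiteMissing, object@maxIndivMissing)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "missingness fractions must be in [0,1]")
  if (!is.na(object@mafMin) && (object@mafMin < 0 || object@mafMin > 0.5))
    msg <- c(msg, "mafMin must be in [0, 0.5] or NA")
  if (object@depthMin > object@depthMax) msg <- c(msg, "depthMin > depthMax")
  if (object@ldStep > object@ldWindow) msg <- c(msg, "ldStep > ldWindow")
  if (object@ldVif <= 1) msg <- c(msg, "ldVif must exceed 1")
  if (length(msg)) msg else TRUE
})

#' @param maxAlleles,maxSiteMissing,depthMin,depthMax,maxIndivMissing,mafMin,ldWindow,ldStep,ldVif,excludeSites
#'   see the slot documentation in [FilterSpec-class].
#' @return A `FilterSpec` object.
#' @rdname FilterSpec-class
#' @examples
#' FilterSpec(mafMin = NA)  # keep rare variants for demographic inference
#' @export
FilterSpec <- function(maxAlleles = 2L, maxSiteMissing = 0.25, depthMin = 6,
                       depthMax = 100, maxIndivMissing = 0.45, mafMin = 0.03,
                       ldWindow = 50L, ldStep = 5L, ldVif = 2,
                       excludeSites = character()) {
  new("FilterSpec", maxAlleles = as.integer(maxAlleles),
      maxSiteMissing = maxSiteMissing, depthMin = depthMin,
      depthMax = depthMax, maxIndivMissing = maxIndivMissing,
      mafMin = as.numeric(mafMin), ldWindow = as.integer(ldWindow),
      ldStep = as.integer(ldStep), ldVif = ldVif,
      excludeSites = as.character(excludeSites))
}

#' Folded site frequency spectrum
#'
#' Counts of SNPs per minor-allele copy-number class for one population
#' sample of `nIndividuals` diploids (2n gene copies). `counts[i + 1]` is the
#' number of SNPs whose minor allele is present in `i` copies, for
#' `i = 0 .. nIndividuals`; class 0 (monomorphic) is usually zero for SNP
#' data, with invariant sites optionally carried in `nMonomorphic`.
#'
#' @slot counts numeric vector of length `nIndividuals + 1`.
#' @slot nIndividuals diploid sample size.
#' @slot nMonomorphic optional count of monomorphic sites surveyed.
#' @export
setClass("FoldedSFS",
  representation(counts = "numeric", nIndividuals = "integer",
                 nMonomorphic = "numeric"),
  prototype(nMonomorphic = NA_real_))

setValidity("FoldedSFS", function(object) {
  msg <- character()
  if (length(object@counts) != object@nIndividuals + 1L)
    msg <- c(msg, "counts must have length nIndividuals + 1")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param counts,nIndividuals,nMonomorphic see slots in [FoldedSFS-class].
#' @return A `FoldedSFS` object.
#' @rdname FoldedSFS-class
#' @export
FoldedSFS <- function(counts, nIndividuals, nMonomorphic = NA_real_) {
  new("FoldedSFS", counts = as.numeric(counts),
      nIndividuals = as.integer(nIndividuals),
      nMonomorphic = as.numeric(nMonomorphic))
}

.MODEL_FREE_PARAMS <- list(
  A = character(0),
  B = c("nAnc", "tBot"),
  C = c("nAnc", "tBot", "gR"),
  D = c("nAnc", "nBot", "tBot", "tEndBot"))

.DEFAULT_BOUNDS <- list(
  nAnc    = c(1e3, 1e7),
  nBot    = c(1e2, 1e7),
  tBot    = c(50, 1000),
  tEndBot = c(1, 999),
  gR      = c(-1e-3, 1e-3))

#' Single-population piecewise demographic model
#'
#' One of four backwards-in-time population size histories, all anchored at a
#' fixed contemporary diploid effective size `nCur`:
#' \describe{
#'   \item{A}{constant size `nCur` at all times (null model, 0 free
#'     parameters).}
#'   \item{B}{size `nCur` until `tBot` generations ago, ancestral size
#'     `nAnc` before that (an abrupt reduction at `tBot`, forward in time).}
#'   \item{C}{as B, but the recent epoch grows exponentially:
#'     `N(t) = nCur * exp(gR * t)` for `t < tBot`. Negative `gR` shrinks the
#'     size going backwards, i.e. a forward-time expansion after the
#'     bottleneck.}
#'   \item{D}{full bottleneck: size `nCur` until `tEndBot`, bottleneck size
#'     `nBot` on `[tEndBot, tBot)`, ancestral size `nAnc` before `tBot`.}
#' }
#' Free parameters and default search bounds: `nAnc`, `nBot` in
#' `[1e2/1e3, 1e7]` (searched on log10 scale), `tBot` in `[50, 1000]`
#' generations, `tEndBot` in `[1, 999]` with `tEndBot < tBot` enforced, and
#' `gR` in `[-1e-3, 1e-3]` per generation.
#'
#' @slot modelId one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @slot nCur fixed contemporary diploid effective size.
#' @slot bounds named list of `c(lower, upper)` per free parameter.
#' @export
setClass("DemographicModel",
  representation(modelId = "character", nCur = "numeric", bounds = "list"))

setValidity("DemographicModel", function(object) {
  msg <- character()
  if (!object@modelId %in% names(.MODEL_FREE_PARAMS))
    msg <- c(msg, "modelId must be one of A, B, C, D")
  if (object@nCur <= 0) msg <- c(msg, "nCur must be positive")
  fp <- .MODEL_FREE_PARAMS[[object@modelId]]
  if (!is.null(fp) && !all(fp %in% names(object@bounds)))
    msg <- c(msg, "bounds missing for some free parameters")
  for (b in object@bounds)
    if (length(b) != 2 || b[1] >= b[2]) {
      msg <- c(msg, "each bound must be c(lower, upper) with lower < upper")
      break
    }
  if (length(msg)) msg else TRUE
})

#' @param modelId,nCur see slots in [DemographicModel-class].
#' @param bounds named list overriding the default search bounds.
#' @return A `DemographicModel` object.
#' @rdname DemographicModel-class
#' @examples
#' demographicModel("B", nCur = 206750)
#' @export
demographicModel <- function(modelId, nCur, bounds = list()) {
  modelId <- match.arg(modelId, c("A", "B", "C", "D"))
  fp <- .MODEL_FREE_PARAMS[[modelId]]
  b <- .DEFAULT_BOUNDS[fp]
  b[names(bounds)] <- bounds
  new("DemographicModel", modelId = modelId, nCur = nCur, bounds = b)
}

#' Free parameters of a demographic model
#' @param model a [DemographicModel-class].
#' @return Character vector of free parameter names.
#' @export
freeParams <- function(model) .MODEL_FREE_PARAMS[[model@modelId]]
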