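#' Configuration for the synthetic-data generators
#'
#' Bundles the scenario and its parameters for [simGenotypes()] and
#' [simBottleneckSFS()]. Defaults emulate a RAD-like SNP study of a recently
#' introduced insect: tens of diploid individuals, a few thousand unlinked
#' biallelic loci strewn on one pseudo-chromosome, ~5% missing genotypes, a
#' contemporary effective size of 2e5 and, for bottleneck scenarios, a
#' five-fold size reduction 200 generations ago.
#'
#' @param scenario one of `"panmictic"`, `"two_deme_island"`,
#'   `"bottleneck_B"`, `"bottleneck_C"`, `"full_D"`.
#' @param nIndividuals diploid individuals per population.
#' @param nSnps number of biallelic loci (one SNP each).
#' @param nCur contemporary diploid effective size.
#' @param tBot,sizeRatio,gR,nBot,tEndBot bottleneck parameters: time of the
#'   size reduction (generations), `nAnc / nCur` ratio, backwards-time
#'   exponential rate for the C scenario, bottleneck size and end time for
#'   the D scenario.
#' @param fst target differentiation of the two-deme island scenario (the
#'   Balding-Nichols F parameter).
#' @param missingness per-genotype missing probability in `[0, 1]`.
#' @param chromLength pseudo-chromosome length in bp over which loci are
#'   placed (2e9 yields ~200 non-empty 10-Mbp windows at the default SNP
#'   count).
#' @param seed RNG seed.
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(scenario = c("panmictic", "two_deme_island",
                                   "bottleneck_B", "bottleneck_C", "full_D"),
                      nIndividuals = 20L, nSnps = 2000L, nCur = 2e5,
                      tBot = 200, sizeRatio = 5, gR = -1e-5, nBot = nCur / 10,
                      tEndBot = 50, fst = 0.1, missingness = 0.05,
                      chromLength = 2e9, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(nIndividuals >= 2L, nSnps >= 1L, nCur > 0, tBot > 0,
            sizeRatio > 0, missingness >= 0, missingness <= 1,
            fst > 0, fst < 1, chromLength >= nSnps)
  structure(list(scenario = scenario, nIndividuals = as.integer(nIndividuals),
                 nSnps = as.integer(nSnps), nCur = nCur, tBot = tBot,
                 sizeRatio = sizeRatio, gR = gR, nBot = nBot,
                 tEndBot = tEndBot, fst = fst, missingness = missingness,
                 chromLength = chromLength, seed = as.integer(seed)),
            class = "SimConfig")
}

# demographic model + free parameters implied by a bottleneck scenario
scenarioModel <- function(cfg) {
  switch(cfg$scenario,
    panmictic = list(model = demographicModel("A", nCur = cfg$nCur),
                     params = numeric(0)),
    bottleneck_B = list(model = demographicModel("B", nCur = cfg$nCur),
                        params = c(nAnc = cfg$nCur * cfg$sizeRatio,
                                   tBot = cfg$tBot)),
    bottleneck_C = list(model = demographicModel("C", nCur = cfg$nCur),
                        params = c(nAnc = cfg$nCur * cfg$sizeRatio,
                                   tBot = cfg$tBot, gR = cfg$gR)),
    full_D = list(model = demographicModel("D", nCur = cfg$nCur),
                  params = c(nAnc = cfg$nCur * cfg$sizeRatio,
                             nBot = cfg$nBot, tBot = cfg$tBot,
                             tEndBot = cfg$tEndBot)),
    stop("scenario has no single-population model: ", cfg$scenario))
}

# haplotypes (loci x 2n of 0/1) to diploid genotypes (individuals x loci)
hapToGenotypes <- function(hap) {
  n <- ncol(hap) / 2L
  t(hap[, 2 * seq_len(n) - 1L, drop = FALSE] +
      hap[, 2 * seq_len(n), drop = FALSE])
}

#' Generate a structured synthetic genotype matrix with truth record
#'
#' Single-population scenarios (`panmictic` and the bottleneck family) draw
#' genotypes from the package's coalescent simulator (one mutation per
#' locus); the `two_deme_island` scenario uses the Balding-Nichols F-model
#' (ancestral frequencies from a Beta(0.5, 0.5), deme frequencies from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)`, Hardy-Weinberg genotypes within demes),
#' whose F parameter is the true FST regime. Loci monomorphic in the sample
#' are redrawn; positions are placed uniformly on one pseudo-chromosome;
#' missing genotypes are planted completely at random.
#'
#' @param cfg a [simConfig()] object.
#' @return List with `gm` (a [GenotypeMatrix-class]) and `truth` (scenario,
#'   generating parameters, `trueK`, `trueFst`).
#' @export
simGenotypes <- function(cfg = simConfig()) {
  n <- cfg$nIndividuals
  L <- cfg$nSnps
  if (cfg$scenario == "two_deme_island") {
    gt <- withSeed(cfg$seed, {
      F <- cfg$fst
      draw <- function(m) {
        p0 <- rbeta(m, 0.5, 0.5)
        p1 <- rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
        p2 <- rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
        g1 <- matrix(rbinom(n * m, 2, rep(p1, each = n)), n, m)
        g2 <- matrix(rbinom(n * m, 2, rep(p2, each = n)), n, m)
        rbind(g1, g2)
      }
      g <- draw(L)
      repeat {
        mono <- colSums(g) %in% c(0L, 4L * n) # fixed across both demes
        if (!any(mono)) break
        g[, mono] <- draw(sum(mono))
      }
      g
    })
    pops <- rep(c("deme1", "deme2"), each = n)
    trueK <- 2L
    trueFst <- cfg$fst
    truthParams <- list(fst = cfg$fst)
  } else {
    sm <- scenarioModel(cfg)
    ep <- modelEpochs(sm$model, sm$params)
    gt <- withSeed(cfg$seed,
      hapToGenotypes(.coalSimHaplotypes(2L * n, ep$start, ep$size,
                                        ep$growth, L)))
    pops <- rep("pop1", n)
    trueK <- 1L
    trueFst <- 0
    truthParams <- as.list(sm$params)
  }
  nInd <- nrow(gt)
  pos <- withSeed(cfg$seed + 1L,
                  sort(sample.int(cfg$chromLength, L)))
  if (cfg$missingness > 0) {
    gt <- withSeed(cfg$seed + 2L, {
      drop <- matrix(runif(nInd * L) < cfg$missingness, nInd, L)
      gt[drop] <- NA_integer_
      gt
    })
  }
  gm <- GenotypeMatrix(gt, chrom = "chr1", pos = pos, popLabels = pops)
  list(gm = gm,
       truth = list(scenario = cfg$scenario, params = truthParams,
                    trueK = trueK, trueFst = trueFst, seed = cfg$seed))
}

#' Generate a folded SFS under a bottleneck scenario with truth record
#'
#' @param cfg a [simConfig()] with scenario `bottleneck_B`, `bottleneck_C` or
#'   `full_D`.
#' @return List with `sfs` (a [FoldedSFS-class]), `model`, `params` (the
#'   generating truth) and `truth`.
#' @export
simBottleneckSFS <- function(cfg = simConfig("bottleneck_B")) {
  if (!cfg$scenario %in% c("bottleneck_B", "bottleneck_C", "full_D"))
    stop("simBottleneckSFS requires a bottleneck scenario")
  sm <- scenarioModel(cfg)
  sfs <- simulateSFS(sm$model, sm$params, cfg$nIndividuals, cfg$nSnps,
                     seed = cfg$seed)
  list(sfs = sfs, model = sm$model, params = sm$params,
       truth = list(scenario = cfg$scenario, params = as.list(sm$params),
                    nIndividuals = cfg$nIndividuals, nSnps = cfg$nSnps,
                    seed = cfg$seed))
}

#' Generate a host-plant survey with planted preference weights
#'
#' Attacks are allocated by weighted sampling without replacement from the
#' pool of available plants, each plant's weight being its taxon's preference
#' weight; the truth labels follow the weights (`> 1` preference, `= 1`
#' proportional, `< 1` avoidance).
#'
#' @param availability data.frame with columns `site`, `taxon`, `available`,
#'   or a named vector of per-taxon counts (treated as one site).
#' @param weights named positive preference weights per taxon (default 1).
#' @param nAttacks total attacks to allocate (> 0, at most the plant total).
#' @param seed RNG seed.
#' @return List with `survey` (site, taxon, available, attacked) and `truth`
#'   (weights and planted classification per taxon).
#' @export
simHostSurvey <- function(availability, weights = NULL, nAttacks,
                          seed = 1L) {
  if (!is.data.frame(availability))
    availability <- data.frame(site = "site1",
                               taxon = names(availability),
                               available = as.vector(availability))
  if (nAttacks <= 0) stop("empty survey: nAttacks must be positive")
  if (nAttacks > sum(availability$available))
    stop("nAttacks exceeds the number of available plants")
  taxa <- unique(availability$taxon)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(taxa)), taxa)
  if (any(weights <= 0)) stop("preference weights must be positive")
  rowIdx <- rep(seq_len(nrow(availability)), availability$available)
  w <- weights[availability$taxon[rowIdx]]
  hit <- withSeed(seed, sample(length(rowIdx), nAttacks, prob = w))
  attacked <- tabulate(rowIdx[hit], nbins = nrow(availability))
  survey <- data.frame(availability[c("site", "taxon", "available")],
                       attacked = attacked)
  planted <- ifelse(weights > 1, "preference",
                    ifelse(weights < 1, "avoidance", "proportional"))
  list(survey = survey,
       truth = list(weights = weights, planted = planted, seed = seed))
}

#' Generate a pair of habitat-suitability grids with a target overlap regime
#'
#' Grids are built from Gaussian suitability kernels: `identical` duplicates
#' one kernel, `disjoint` places two kernels on complementary halves of the
#' grid (zero elsewhere), and `partial` mixes a shared and a private kernel
#' with the given fraction.
#'
#' @param overlap `"identical"`, `"disjoint"` or `"partial"`.
#' @param shape grid dimensions `c(rows, cols)`.
#' @param mixing for `"partial"`, the weight of the shared kernel in the
#'   second grid, in (0, 1).
#' @param seed RNG seed for kernel placement.
#' @return List of two numeric matrices `a` and `b` with values in `[0, 1]`.
#' @export
simSuitabilityPair <- function(overlap = c("identical", "disjoint",
                                           "partial"),
                               shape = c(30L, 30L), mixing = 0.5,
                               seed = 1L) {
  overlap <- match.arg(overlap)
  nr <- shape[1]; nc <- shape[2]
  kernel <- function(cr, cc, s) {
    outer(seq_len(nr), seq_len(nc), function(r, c)
      exp(-((r - cr)^2 + (c - cc)^2) / (2 * s^2)))
  }
  centers <- withSeed(seed, runif(4, 0.25, 0.75))
  sL <- max(2, nr / 8)
  if (overlap == "identical") {
    a <- kernel(centers[1] * nr, centers[2] * nc, sL)
    b <- a
  } else if (overlap == "disjoint") {
    a <- kernel(nr * 0.5, nc * 0.25, sL)
    b <- kernel(nr * 0.5, nc * 0.75, sL)
    a[, (nc %/% 2 + 1):nc] <- 0
    b[, 1:(nc %/% 2)] <- 0
  } else {
    shared <- kernel(centers[1] * nr, centers[2] * nc, sL)
    private <- kernel(centers[3] * nr, centers[4] * nc, sL)
    a <- shared
    b <- mixing * shared + (1 - mixing) * private
  }
  list(a = a / max(a), b = b / max(b))
}
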