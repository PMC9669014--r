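.cache <- new.env(parent = emptyenv())

# Validate free parameters and expand a model into backwards-time epochs
# (start, size, growth); the final epoch always has growth 0.
modelEpochs <- function(model, params = numeric()) {
  id <- model@modelId
  fp <- freeParams(model)
  miss <- setdiff(fp, names(params))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  p <- as.list(params)
  nCur <- model@nCur
  sizes <- c(nCur, p$nAnc, p$nBot)
  if (any(unlist(sizes) <= 0)) stop("invalid parameter: population sizes must be positive")
  ep <- switch(id,
    A = list(start = 0, size = nCur, growth = 0),
    B = list(start = c(0, p$tBot), size = c(nCur, p$nAnc), growth = c(0, 0)),
    C = list(start = c(0, p$tBot), size = c(nCur, p$nAnc),
             growth = c(p$gR, 0)),
    D = {
      if (!(p$tEndBot < p$tBot))
        stop("invalid parameter: tEndBot must be smaller than tBot")
      list(start = c(0, p$tEndBot, p$tBot),
           size = c(nCur, p$nBot, p$nAnc), growth = c(0, 0, 0))
    })
  if (any(diff(ep$start) <= 0)) stop("invalid parameter: epoch times must increase")
  if (any(ep$start < 0)) stop("invalid parameter: times must be nonnegative")
  ep
}

#' Piecewise population-size trajectory of a demographic model
#'
#' @param model a [DemographicModel-class].
#' @param params named numeric vector of the model's free parameters.
#' @return A vectorized function `N(t)` giving the diploid effective size
#'   `t` generations before present.
#' @examples
#' m <- demographicModel("B", nCur = 206750)
#' N <- sizeTrajectory(m, c(nAnc = 1044983, tBot = 114))
#' N(c(100, 200))  # 206750 before the bottleneck time, 1044983 beyond
#' @export
sizeTrajectory <- function(model, params = numeric()) {
  ep <- modelEpochs(model, params)
  function(t) {
    e <- findInterval(t, ep$start)
    ep$size[e] * exp(ep$growth[e] * (t - ep$start[e]))
  }
}

#' Simulate a folded SFS under a demographic model
#'
#' Coalescent genealogies for `2 * nIndividuals` gene copies are simulated
#' under the model's size history by standard time rescaling (exponential
#' waiting times with intensity `C(k,2) / 2N(t)`, integrated analytically
#' across piecewise/exponential epochs). Loci are ascertained proportionally
#' to total tree length — in the low-mutation limit a locus carries a SNP
#' with probability proportional to its genealogy's length, which is how
#' single-SNP-per-locus data arise — and one mutation is then dropped
#' uniformly on the tree of each retained locus, folded and accumulated. The
#' resulting class counts are multinomial with probabilities
#' `E[L_i] / E[L_total]`, matching [expectedSFS()].
#'
#' @param model a [DemographicModel-class].
#' @param params named free-parameter values.
#' @param nIndividuals diploid sample size (>= 2).
#' @param nSnps number of SNPs (= independent loci) to simulate.
#' @param seed RNG seed.
#' @return A [FoldedSFS-class]; its counts sum exactly to `nSnps`.
#' @export
simulateSFS <- function(model, params, nIndividuals, nSnps, seed = 1L) {
  stopifnot(nIndividuals >= 2L, nSnps >= 1L)
  ep <- modelEpochs(model, params)
  counts <- withSeed(seed,
    .coalSimSFS(2L * nIndividuals, ep$start, ep$size, ep$growth,
                as.integer(nSnps)))
  FoldedSFS(counts, nIndividuals)
}

#' Pairwise coalescence times under a model
#'
#' Simulates waiting times to coalescence for a sample of two gene copies;
#' under a constant size N their mean is 2N generations.
#'
#' @inheritParams simulateSFS
#' @param nRep number of replicate pairs.
#' @return Numeric vector of coalescence times in generations.
#' @export
pairCoalescenceTimes <- function(model, params, nRep, seed = 1L) {
  ep <- modelEpochs(model, params)
  withSeed(seed, .coalPairTimes(ep$start, ep$size, ep$growth,
                                as.integer(nRep)))
}

# --- analytic expected SFS -------------------------------------------------
# In rescaled time tau = int dt / 2N(t) the ancestral lineage-count process
# is the standard pure-death process with rates C(k,2). Its state
# probabilities are solved once per sample size on a fixed tau grid
# (deSolve::lsoda) and cached; the expected real time spent with k lineages
# under any size history is then E[T_k] = int P_k(tau) * 2N(t(tau)) dtau.
deathProcessGrid <- function(K) {
  key <- paste0("death", K)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  tau <- c(0, exp(seq(log(1e-7), log(60), length.out = 3500)))
  lam <- function(k) k * (k - 1) / 2
  nState <- K - 1L  # states k = 2..K
  y0 <- c(rep(0, nState - 1L), 1)
  deriv <- function(t, y, parms) {
    k <- 2:K
    inflow <- c(lam(3:K) * y[-1], 0)
    list(inflow - lam(k) * y)
  }
  sol <- deSolve::lsoda(y0, tau, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  P <- pmax(sol[, -1, drop = FALSE], 0)  # grid x states (k = 2..K)
  # trapezoid weights folded into the state matrix: E[T_k] is then a single
  # matrix-vector product with the midpoint values of 2N(t(tau))
  nG <- nrow(P)
  Pmid <- (P[-1, , drop = FALSE] + P[-nG, , drop = FALSE]) / 2 * diff(tau)
  out <- list(tau = tau, P = P, PmidT = t(Pmid))
  .cache[[key]] <- out
  out
}

# B[i, k] = k * P(a branch with k ancestral lineages subtends i of K samples)
sizeClassMatrix <- function(K) {
  key <- paste0("class", K)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  i <- seq_len(K - 1L)
  k <- 2:K
  B <- outer(i, k, function(i, k)
    k * exp(lchoose(K - i - 1, k - 2) - lchoose(K - 1, k - 1)))
  .cache[[key]] <- B
  B
}

# 2N(t(tau)) on the tau grid for a piecewise-exponential history
rescaledSize <- function(ep, tau) {
  nE <- length(ep$start)
  tauB <- 0
  if (nE > 1) {
    dTau <- numeric(nE - 1)
    for (e in seq_len(nE - 1)) {
      dt <- ep$start[e + 1] - ep$start[e]
      g <- ep$growth[e]; N0 <- ep$size[e]
      dTau[e] <- if (g == 0) dt / (2 * N0) else
        (1 - exp(-g * dt)) / (2 * N0 * g)
    }
    tauB <- c(0, cumsum(dTau))
  }
  e <- findInterval(tau, tauB, rightmost.closed = FALSE)
  e[e < 1] <- 1
  u <- tau - tauB[e]
  g <- ep$growth[e]; N0 <- ep$size[e]
  ifelse(g == 0, 2 * N0, 2 * N0 / pmax(1 - 2 * N0 * g * u, 1e-300))
}

#' Expected folded SFS proportions under a demographic model
#'
#' Two engines. `"analytic"` integrates the expected time the ancestral
#' process spends with k lineages against the cached standard death-process
#' solution (exact topology mixture, deterministic and smooth in the
#' parameters); `"simulation"` Monte-Carlo averages per-class branch lengths
#' over `nSims` coalescent genealogies, mirroring a simulation-based
#' composite-likelihood workflow.
#'
#' @inheritParams simulateSFS
#' @param engine `"analytic"` or `"simulation"`.
#' @param nSims genealogies for the simulation engine (default 1e5).
#' @param seed RNG seed (simulation engine only).
#' @return Numeric vector of expected proportions over folded polymorphic
#'   classes `1 .. nIndividuals`, summing to 1.
#' @export
expectedSFS <- function(model, params, nIndividuals,
                        engine = c("analytic", "simulation"),
                        nSims = 1e5, seed = 1L) {
  engine <- match.arg(engine)
  K <- 2L * nIndividuals
  ep <- modelEpochs(model, params)
  if (engine == "analytic") {
    dp <- deathProcessGrid(K)
    w <- rescaledSize(ep, dp$tau)
    wMid <- (w[-1] + w[-length(w)]) / 2
    eT <- as.vector(dp$PmidT %*% wMid)
    eL <- as.vector(sizeClassMatrix(K) %*% eT)
  } else {
    eL <- withSeed(seed,
      .coalBranchLengths(K, ep$start, ep$size, ep$growth,
                         as.integer(nSims)))[-1]
  }
  n <- nIndividuals
  folded <- numeric(n)
  for (j in seq_len(n))
    folded[j] <- if (j < K - j) eL[j] + eL[K - j] else eL[j]
  folded / sum(folded)
}

#' Composite log-likelihood of an observed folded SFS
#'
#' Multinomial log-likelihood over polymorphic classes, `sum_i m_i log p_i`
#' in nats, treating SNPs as independent (composite likelihood). Expected
#' proportions are floored at 1e-8 and renormalized so that classes with no
#' simulated mass cannot produce infinite penalties.
#'
#' @param obs a [FoldedSFS-class].
#' @param expectedProportions expected proportions over folded classes
#'   `1 .. n` (e.g. from [expectedSFS()]).
#' @return Log-likelihood in nats.
#' @export
compositeLogLik <- function(obs, expectedProportions) {
  m <- sfsCounts(obs)[-1]
  if (length(m) != length(expectedProportions))
    stop("expected proportions must cover classes 1 .. n")
  if (sum(m) == 0) stop("observed SFS has no polymorphic sites")
  p <- pmax(expectedProportions, 1e-8)
  p <- p / sum(p)
  sum(m * log(p))
}

# parameter transform for the line searches: sizes on log10 scale
.isSizeParam <- function(p) p %in% c("nAnc", "nBot")
.toOpt <- function(p, x) if (.isSizeParam(p)) log10(x) else x
.fromOpt <- function(p, x) if (.isSizeParam(p)) 10^x else x

#' Fit a demographic model to a folded SFS by cyclic Brent search
#'
#' Maximizes the composite log-likelihood over the model's free parameters:
#' each replicate starts from a random point inside the search bounds
#' (log-uniform for the size parameters, which are searched on a log10
#' scale) and runs up to `nCycles` cycles of one-dimensional bounded Brent
#' optimization over each free parameter in turn, stopping early when a full
#' cycle improves the log-likelihood by less than `cycleTol`. The best
#' replicate is reported with `AIC = 2k - 2 lnL`.
#'
#' For model D the constraint `tEndBot < tBot` is enforced by clipping each
#' parameter's search interval against the other's current value. With
#' `engine = "simulation"` each replicate reuses one simulation seed across
#' evaluations (common random numbers), keeping the Monte-Carlo likelihood
#' surface coherent for the line searches.
#'
#' @param obs observed [FoldedSFS-class].
#' @param model a [DemographicModel-class] (its `nCur` stays fixed).
#' @param engine,nSims passed to [expectedSFS()].
#' @param nCycles Brent cycles per replicate (default 40).
#' @param nReps random restarts (default 10).
#' @param starts optional list of named start vectors; overrides the random
#'   starts and sets `nReps = length(starts)`.
#' @param seed RNG seed.
#' @param cycleTol early-stop tolerance on per-cycle lnL improvement.
#' @return List with `modelId`, `model`, `paramsHat`, `lnL`, `aic`, `k`
#'   (free-parameter count), `engine`, and `reps`, a data.frame of
#'   per-replicate results.
#' @export
fitModel <- function(obs, model, engine = c("analytic", "simulation"),
                     nCycles = 40L, nSims = 1e5, nReps = 10L, starts = NULL,
                     seed = 1L, cycleTol = 1e-6) {
  engine <- match.arg(engine)
  fp <- freeParams(model)
  n <- sfsSampleSize(obs)
  kFree <- length(fp)

  if (!is.null(starts)) nReps <- length(starts)
  seeds <- subSeeds(seed, 2L * nReps)

  evalLnL <- function(params, simSeed) {
    p <- tryCatch(
      expectedSFS(model, params, n, engine = engine, nSims = nSims,
                  seed = simSeed),
      error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    ll <- compositeLogLik(obs, p)
    if (!is.finite(ll)) -Inf else ll
  }

  if (kFree == 0L) {
    ll <- evalLnL(numeric(0), seeds[1])
    reps <- data.frame(rep = 1L, lnL = ll, aic = -2 * ll)
    return(list(modelId = model@modelId, model = model,
                paramsHat = numeric(0), lnL = ll, aic = -2 * ll, k = 0L,
                engine = engine, reps = reps))
  }

  bounds <- model@bounds[fp]
  drawStart <- function(s) withSeed(s, {
    v <- vapply(fp, function(p) {
      b <- .toOpt(p, bounds[[p]])
      runif(1, b[1], b[2])
    }, numeric(1))
    v <- stats::setNames(vapply(fp, function(p)
      .fromOpt(p, v[[p]]), numeric(1)), fp)
    if (all(c("tBot", "tEndBot") %in% fp) && v["tEndBot"] >= v["tBot"])
      v["tEndBot"] <- v["tBot"] * runif(1, 0.1, 0.9)
    v
  })

  repRows <- vector("list", nReps)
  best <- NULL
  for (r in seq_len(nReps)) {
    params <- if (!is.null(starts)) {
      s <- unlist(starts[[r]])[fp]
      stats::setNames(as.numeric(s), fp)
    } else drawStart(seeds[r])
    simSeed <- seeds[nReps + r]
    ll <- evalLnL(params, simSeed)
    for (cycle in seq_len(nCycles)) {
      prev <- ll
      for (p in fp) {
        b <- bounds[[p]]
        lo <- b[1]; hi <- b[2]
        if (p == "tEndBot") hi <- min(hi, params[["tBot"]] * 0.999)
        if (p == "tBot" && "tEndBot" %in% fp)
          lo <- max(lo, params[["tEndBot"]] * 1.001)
        if (lo >= hi) next
        f <- function(x) {
          pp <- params
          pp[p] <- .fromOpt(p, x)
          evalLnL(pp, simSeed)
        }
        int <- c(.toOpt(p, lo), .toOpt(p, hi))
        opt <- stats::optimize(f, interval = int, maximum = TRUE,
                               tol = max(1e-8, diff(int) * 1e-4))
        if (opt$objective > ll) {
          params[p] <- .fromOpt(p, opt$maximum)
          ll <- opt$objective
        }
      }
      if (ll - prev < cycleTol) break
    }
    repRows[[r]] <- data.frame(rep = r, lnL = ll, aic = 2 * kFree - 2 * ll,
                               t(params))
    if (is.null(best) || ll > best$lnL)
      best <- list(params = params, lnL = ll)
  }
  reps <- do.call(rbind, repRows)
  list(modelId = model@modelId, model = model, paramsHat = best$params,
       lnL = best$lnL, aic = 2 * kFree - 2 * best$lnL, k = kFree,
       engine = engine, reps = reps)
}

#' AIC model selection across fitted demographic models
#'
#' Rescales AIC values to differences `delta_i = AIC_i - AIC_min`, computes
#' Akaike weights `w_i = exp(-delta_i / 2) / sum`, tallies the fraction of
#' replicate optimization runs in which each model attains the lowest AIC
#' (selection frequency), and flags models within `deltaThreshold` units of
#' the best as jointly supported (a difference below ~3 units does not allow
#' a unique model choice).
#'
#' @param fits list of [fitModel()] results on the same observed SFS.
#' @param deltaThreshold joint-support threshold on delta AIC (default 3).
#' @return data.frame with one row per model: `model`, `k`, `lnL`, `aic`,
#'   `delta`, `weight`, `selectionFreq`, `jointlySupported`.
#' @export
modelSelection <- function(fits, deltaThreshold = 3) {
  if (length(fits) < 2L) stop("model selection needs at least 2 fitted models")
  ids <- vapply(fits, `[[`, character(1), "modelId")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  nRep <- min(vapply(fits, function(f) nrow(f$reps), integer(1)))
  repAic <- vapply(fits, function(f) f$reps$aic[seq_len(nRep)], numeric(nRep))
  repAic <- matrix(repAic, nrow = nRep)
  selFreq <- tabulate(apply(repAic, 1, which.min), ncol(repAic)) / nRep
  data.frame(model = ids, k = vapply(fits, `[[`, integer(1), "k"),
             lnL = vapply(fits, `[[`, numeric(1), "lnL"),
             aic = aic, delta = delta, weight = w, selectionFreq = selFreq,
             jointlySupported = delta < deltaThreshold)
}

#' Parametric bootstrap confidence intervals for a fitted model
#'
#' Simulates `nBoot` folded SFS datasets at the fitted parameter values (same
#' sample size and SNP count as requested), refits the model to each starting
#' from the fitted values, and reports percentile intervals per parameter.
#' Replicates whose refit fails are dropped with a warning; at least 80%
#' successes are required.
#'
#' @param fit a [fitModel()] result.
#' @param nIndividuals,nSnps size of each simulated dataset.
#' @param nBoot bootstrap replicates (default 100).
#' @param nCycles Brent cycles per refit (fewer than a de novo fit since the
#'   starting point is the fitted optimum).
#' @param alpha two-sided interval level.
#' @param seed RNG seed.
#' @return List with `ci` (data.frame: param, low, high), `estimates`
#'   (replicates x params), `nBoot`, `nSuccess`.
#' @export
parametricBootstrap <- function(fit, nIndividuals, nSnps, nBoot = 100L,
                                nCycles = 15L, alpha = 0.05, seed = 1L) {
  fp <- freeParams(fit$model)
  if (!length(fp)) stop("model has no free parameters to bootstrap")
  seeds <- subSeeds(seed, 2L * nBoot)
  est <- matrix(NA_real_, nBoot, length(fp), dimnames = list(NULL, fp))
  for (b in seq_len(nBoot)) {
    res <- tryCatch({
      sim <- simulateSFS(fit$model, fit$paramsHat, nIndividuals, nSnps,
                         seed = seeds[b])
      re <- fitModel(sim, fit$model, engine = fit$engine,
                     nCycles = nCycles, starts = list(fit$paramsHat),
                     seed = seeds[nBoot + b])
      re$paramsHat
    }, error = function(e) NULL)
    if (!is.null(res) && all(is.finite(res))) est[b, ] <- res[fp]
  }
  ok <- stats::complete.cases(est)
  if (sum(ok) < nBoot) warning(nBoot - sum(ok), " bootstrap refits failed")
  if (sum(ok) < 0.8 * nBoot)
    stop("fewer than 80% of bootstrap refits succeeded")
  ci <- data.frame(param = fp,
                   low = apply(est[ok, , drop = FALSE], 2,
                               stats::quantile, alpha / 2),
                   high = apply(est[ok, , drop = FALSE], 2,
                                stats::quantile, 1 - alpha / 2))
  rownames(ci) <- NULL
  list(ci = ci, estimates = est[ok, , drop = FALSE], nBoot = nBoot,
       nSuccess = sum(ok))
}

#' Convert generations to years
#'
#' @param g generations.
#' @param genPerYear generations per year (default 5.5, typical of
#'   multivoltine mealybugs in the tropics).
#' @return List with `years` (raw) and `yearsRounded`.
#' @examples
#' generationsToYears(114)  # ~21 years
#' @export
generationsToYears <- function(g, genPerYear = 5.5) {
  if (genPerYear <= 0) stop("genPerYear must be positive")
  y <- g / genPerYear
  list(years = y, yearsRounded = round(y))
}

#' Bottleneck severity as a fraction of the ancestral size
#'
#' @param nCur contemporary effective size.
#' @param nAnc ancestral effective size (> 0).
#' @return `1 - nCur / nAnc`, the fractional reduction.
#' @examples
#' reductionFraction(206750, 1044983)  # > 0.80
#' @export
reductionFraction <- function(nCur, nAnc) {
  if (nAnc <= 0) stop("nAnc must be positive")
  1 - nCur / nAnc
}

#' Observed folded SFS from a genotype matrix
#'
#' Uses sites genotyped in every individual of the population (one SNP per
#' locus is assumed upstream, e.g. after LD pruning or on RAD loci) and
#' tabulates minor-allele copy classes.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param pop population label; `NULL` pools all individuals.
#' @param nMonomorphic optional count of invariant sites surveyed.
#' @return A [FoldedSFS-class].
#' @export
observedFoldedSFS <- function(gm, pop = NULL, nMonomorphic = NA_real_) {
  gt <- if (is.null(pop)) genotypes(gm) else popGenotypes(gm, pop)
  complete <- colSums(is.na(gt)) == 0L
  gt <- gt[, complete, drop = FALSE]
  n <- nrow(gt)
  cAlt <- colSums(gt)
  minor <- pmin(cAlt, 2L * n - cAlt)
  FoldedSFS(tabulate(minor + 1L, nbins = n + 1L), n, nMonomorphic)
}
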