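#' Principal component analysis of genotypes
#'
#' Missing genotypes are mean-imputed per site, columns are centered
#' (optionally scaled), and individual scores are obtained by
#' eigendecomposition of the individuals-by-individuals covariance of the
#' imputed matrix. Scores are deterministic up to a sign per component.
#'
#' @param gm a [GenotypeMatrix-class] with at least 2 individuals and sites.
#' @param nComponents number of components to return (default all).
#' @param scale also divide each site column by its standard deviation
#'   (zero-variance columns are left unscaled).
#' @return List with `coords` (individuals x components score matrix) and
#'   `varExplained` (fraction of variance per component, non-increasing).
#' @export
pcaGenotypes <- function(gm, nComponents = NULL, scale = FALSE) {
  gt <- genotypes(gm)
  if (nrow(gt) < 2L || ncol(gt) < 2L) stop("PCA needs >= 2 individuals and sites")
  mu <- colMeans(gt, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  X <- gt
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X <- sweep(X, 2, colMeans(X))
  if (scale) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  C <- tcrossprod(X)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  kMax <- sum(lam > max(lam) * 1e-12)
  if (is.null(nComponents)) nComponents <- kMax
  nComponents <- min(nComponents, kMax)
  coords <- e$vectors[, seq_len(nComponents), drop = FALSE] *
    rep(sqrt(lam[seq_len(nComponents)]), each = nrow(X))
  rownames(coords) <- individualIds(gm)
  colnames(coords) <- paste0("PC", seq_len(nComponents))
  list(coords = coords,
       varExplained = lam[seq_len(nComponents)] / sum(lam))
}

# one-hot genotype encoding: n x 3L matrix of indicators and its mask of
# observed entries (a missing genotype masks all three classes of the locus)
encodeOneHot <- function(gt) {
  n <- nrow(gt); L <- ncol(gt)
  X <- matrix(0, n, 3L * L)
  M <- matrix(0, n, 3L * L)
  for (g in 0:2) {
    hit <- which(gt == g, arr.ind = TRUE)
    if (nrow(hit)) X[cbind(hit[, 1], 3L * (hit[, 2] - 1L) + g + 1L)] <- 1
  }
  obs <- which(!is.na(gt), arr.ind = TRUE)
  if (nrow(obs))
    for (g in 0:2)
      M[cbind(obs[, 1], 3L * (obs[, 2] - 1L) + g + 1L)] <- 1
  list(X = X, M = M)
}

# masked multiplicative NMF updates (weighted Lee-Seung). Q starts uniform so
# that the fit is exactly equivariant under permutation of individuals.
nmfFit <- function(X, M, K, maxIter = 200L, tol = 1e-6, seed = 1L,
                   ridge = 0) {
  n <- nrow(X); p <- ncol(X)
  eps <- 1e-12
  G <- withSeed(seed, matrix(runif(K * p, 0.1, 1), K, p))
  Q <- matrix(1 / K, n, K)
  MX <- M * X
  loss <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    P <- Q %*% G
    Q <- Q * (MX %*% t(G)) / ((M * P) %*% t(G) + ridge * Q + eps)
    P <- Q %*% G
    G <- G * (t(Q) %*% MX) / (t(Q) %*% (M * P) + ridge * G + eps)
    P <- Q %*% G
    l <- sum((M * (X - P))^2)
    loss <- c(loss, l)
    if (is.finite(prev) && prev - l < tol * max(prev, 1)) {
      converged <- TRUE
      break
    }
    prev <- l
  }
  list(Q = Q, G = G, loss = loss, converged = converged)
}

# simplex projection of the factors for reporting: Q rows sum to 1, G rows
# sum to 1 within each locus triplet
projectFactors <- function(Q, G) {
  qs <- rowSums(Q)
  qs[qs == 0] <- 1
  Q <- Q / qs
  L <- ncol(G) / 3L
  triplet <- rep(seq_len(L), each = 3L)
  gs <- t(apply(G, 1, function(row) {
    s <- tapply(row, triplet, sum)
    s[s == 0] <- 1
    row / s[triplet]
  }))
  list(Q = Q, G = gs)
}

#' Admixture-style ancestry estimation by nonnegative matrix factorization
#'
#' Factorizes the one-hot genotype encoding into per-individual ancestry
#' proportions Q (rows on the K-simplex) and ancestral genotype-class
#' frequencies G, by masked multiplicative (alternating nonnegative
#' least-squares flavoured) updates; missing genotypes are excluded from the
#' fit loss rather than imputed. The best of `nRuns` seeded runs by in-sample
#' loss is returned. Q starts at the uniform barycenter, so relabelling or
#' permuting individuals permutes Q rows identically.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param K number of ancestral clusters, `1 <= K <=` individuals.
#' @param nRuns independent restarts (differing in the G initialisation).
#' @param maxIter,tol update cap and relative loss tolerance per run.
#' @param ridge optional nonnegative ridge penalty added to the updates.
#' @param seed RNG seed from which per-run seeds derive.
#' @return List with `K`, `Q` (individuals x K, rows summing to 1), `G`,
#'   `loss` (trajectory of the best run), `bestRun`, and `converged` (FALSE
#'   flags a run stopped at `maxIter`).
#' @export
admixtureQ <- function(gm, K, nRuns = 10L, maxIter = 200L, tol = 1e-6,
                       ridge = 0, seed = 1L) {
  stopifnot(K >= 1L, K <= nIndividuals(gm))
  gt <- genotypes(gm)
  enc <- encodeOneHot(gt)
  seeds <- subSeeds(seed, nRuns)
  best <- NULL
  bestRun <- NA_integer_
  for (r in seq_len(nRuns)) {
    fit <- nmfFit(enc$X, enc$M, K, maxIter = maxIter, tol = tol,
                  seed = seeds[r], ridge = ridge)
    if (is.null(best) || tail(fit$loss, 1) < tail(best$loss, 1)) {
      best <- fit
      bestRun <- r
    }
  }
  if (!best$converged)
    warning("NMF did not converge within maxIter; returning best iterate")
  pr <- projectFactors(best$Q, best$G)
  rownames(pr$Q) <- individualIds(gm)
  list(K = K, Q = pr$Q, G = pr$G, loss = best$loss, bestRun = bestRun,
       converged = best$converged)
}

# predicted genotype-class probabilities for individual x locus cells,
# clipped to [1e-6, 1] and renormalized over the three classes
predictGenoProb <- function(Q, G) {
  P <- Q %*% G
  P <- pmin(pmax(P, 1e-6), 1)
  L <- ncol(G) / 3L
  triplet <- rep(seq_len(L), each = 3L)
  for (i in seq_len(nrow(P))) {
    s <- tapply(P[i, ], triplet, sum)
    P[i, ] <- P[i, ] / s[triplet]
  }
  P
}

#' Choose K by masked-genotype cross-entropy
#'
#' For each candidate K, a random fraction of observed genotype entries is
#' held out, the admixture factorization is fit on the remainder, and the
#' held-out entries are scored by the mean negative log predicted probability
#' of the observed genotype class. The K minimising the mean cross-entropy
#' has the best predictive accuracy; as with the cross-entropy criterion in
#' general, it identifies the most predictive K rather than an absolute
#' number of ancestral populations.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param KRange candidate K values (default 1..10 capped at sample size).
#' @param maskedFraction fraction of observed entries to hold out, in (0,1).
#' @param nReps mask/fit repetitions per K.
#' @param nRuns,maxIter,tol passed to the factorization.
#' @param seed RNG seed.
#' @return List with `table` (data.frame: K, meanCE, sdCE) and `bestK`.
#' @export
selectK <- function(gm, KRange = 1:10, maskedFraction = 0.05, nReps = 5L,
                    nRuns = 3L, maxIter = 200L, tol = 1e-6, seed = 1L) {
  stopifnot(maskedFraction > 0, maskedFraction < 1)
  KRange <- KRange[KRange >= 1 & KRange <= nIndividuals(gm)]
  gt <- genotypes(gm)
  enc <- encodeOneHot(gt)
  obsCells <- which(!is.na(gt))
  seeds <- subSeeds(seed, nReps * (length(KRange) + 1L))
  ce <- matrix(NA_real_, nReps, length(KRange))
  n <- nrow(gt)
  for (rep in seq_len(nReps)) {
    heldOut <- withSeed(seeds[rep],
      sample(obsCells, max(1L, round(maskedFraction * length(obsCells)))))
    Mtrain <- enc$M
    # mask the three one-hot columns of each held-out (individual, locus) cell
    ind <- (heldOut - 1L) %% n + 1L
    loc <- (heldOut - 1L) %/% n + 1L
    for (g in 0:2) Mtrain[cbind(ind, 3L * (loc - 1L) + g + 1L)] <- 0
    for (ki in seq_along(KRange)) {
      runSeed <- seeds[nReps + (rep - 1L) * length(KRange) + ki]
      runSeeds <- subSeeds(runSeed, nRuns)
      best <- NULL
      for (r in seq_len(nRuns)) {
        fit <- nmfFit(enc$X, Mtrain, KRange[ki], maxIter = maxIter,
                      tol = tol, seed = runSeeds[r])
        if (is.null(best) || tail(fit$loss, 1) < tail(best$loss, 1)) best <- fit
      }
      pr <- projectFactors(best$Q, best$G)
      P <- predictGenoProb(pr$Q, pr$G)
      gObs <- gt[heldOut]
      pHit <- P[cbind(ind, 3L * (loc - 1L) + gObs + 1L)]
      ce[rep, ki] <- mean(-log(pHit))
    }
  }
  tab <- data.frame(K = KRange, meanCE = colMeans(ce),
                    sdCE = apply(ce, 2, stats::sd))
  list(table = tab, bestK = KRange[which.min(tab$meanCE)])
}
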