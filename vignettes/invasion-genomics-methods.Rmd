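---
title: "Methods: demographic inference and host-use analysis for invasive insect populations"
author: "invagen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic inference and host-use analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invagen)
```

# Scope

`invagen` implements the population-genomic and ecological analyses used to
characterise recently introduced insect populations from RAD-style SNP data
and field host surveys: genotype filtering from VCF, per-population
diversity statistics, ordination and admixture-style clustering,
single-population coalescent demographic inference on the folded site
frequency spectrum (SFS), Neu-method resource-selection analysis, and
niche-overlap indices. A seeded synthetic-data module generates every input
the pipeline consumes, so all stages are testable without external
downloads.

# Genotype container and filters

Genotypes are diploid biallelic alternate-allele counts (0/1/2, `NA` for
missing) held in a `GenotypeMatrix`, a `SummarizedExperiment` with sites in
rows (chromosome, 1-based position, optional mean depth, allele number) and
individuals in columns (population labels).

`filterSites()` applies the standard RAD protocol in a fixed order so that
per-criterion removal counts are well defined: allele number (max 2), site
missingness (< 25%), mean site depth (6-100X, skipped where depth is
unavailable), monomorphic sites, minor allele frequency (>= 0.03 when
enabled), then an external exclusion list — the plug point for outlier-SNP
scans, which are out of scope here. Two datasets are the intended outputs:
one keeping all rare variants (`mafMin = NA`) for demographic inference,
and a MAF-filtered, LD-pruned one for diversity and structure.
`filterIndividuals()` drops individuals with more than 45% missing calls.
All frequency computations are pairwise-complete (missing genotypes are
simply ignored at a site).

`ldPrune()` interprets the conventional PLINK parameters (window 50 sites,
shift 5, VIF 2) as a pairwise criterion: within each sliding window the
later site of any pair with genotype-dosage r² above 1 − 1/VIF = 0.5 is
removed. A pairwise rule was chosen over multi-site VIF regression because
it is reproducible without specifying a regression design and removes the
same duplicated signal; the procedure is deterministic given site order.

# Diversity statistics

Per-site expected heterozygosity uses the Nei unbiased estimator
2p(1−p)·2n/(2n−1); the estimator was chosen because it is the default in
the diversity packages practitioners use, and the small-sample correction
matters at the sample sizes typical of invasion surveys (4–11 diploids per
site). F_IS is the multilocus ratio of averages 1 − mean(Ho)/mean(He) with
a percentile bootstrap over loci (9,999 replicates by default; the locus is
the resampling unit since genotypes within a locus are not exchangeable).
Rarefied allelic richness uses the hypergeometric formula per site and is
reported both as a per-locus mean and a per-dataset sum, since published
tables are ambiguous between the two conventions. Private alleles count
(site, allele) pairs observed in exactly one population.

Nucleotide diversity divides the summed per-site unbiased heterozygosity of
variant sites by the total number of sequenced sites, so it is comparable
to estimates that use variant and invariant sites; `effectiveSize()`
converts it to a long-term diploid effective size via Ne = π/4μ. Note the
contemporary size fixed in the demographic models is a user input, not
derived internally: published fixed values do not always equal π/4μ at the
rounded π printed alongside them, so the package never silently re-derives
one from the other.

Tajima's D is computed in non-overlapping windows (10 Mbp by default) with
the canonical constants at the nominal number of gene copies; per-site
diversity uses the copies actually genotyped. The summary is the mean
across windows with the standard error of that mean. The synthetic
generator places loci on one pseudo-chromosome of 2 Gbp so the default SNP
density yields ~200 windows.

Pairwise F_ST is the Weir–Cockerham variance-components estimator, summed
over loci (ratio of sums), with a percentile bootstrap over loci. Estimates
may be slightly negative and are not truncated.

# Structure

`pcaGenotypes()` mean-imputes missing genotypes per site, centers columns
and eigendecomposes the individual covariance; scores are deterministic up
to sign. `admixtureQ()` is a deliberately simple re-implementation of the
sparse nonnegative matrix factorization family used for ancestry
estimation: the one-hot genotype encoding is factorized by masked
multiplicative updates (missing entries excluded from the loss, unlike
PCA), with no sparsity penalty by default and an optional ridge term. Q
starts at the uniform barycenter so that permuting individuals permutes Q
rows exactly; runs differ in the seeded initialisation of the ancestral
frequencies G. Raw multiplicative updates guarantee a non-increasing loss;
the simplex projection of Q rows (and per-locus normalization of G) is
applied to the reported factors. `selectK()` masks a fraction (5% by
default) of observed genotype entries, refits, and scores held-out entries
by mean negative log predicted probability (predicted class probabilities
clipped to [1e-6, 1] and renormalized); as usual the criterion identifies
the most predictive K, not a biological truth. Exact numerical replication
of published sNMF software is a non-goal; the package's clustering claims
are property-based (correct K regimes, high assignment under strong
divergence).

# Demographic inference on the folded SFS

Four backwards-time size histories anchored at a fixed contemporary size
N_CUR: constant (A), abrupt ancestral step at T_BOT (B), exponential recent
epoch with rate G_R plus ancestral step (C; negative G_R shrinks the size
going backwards, i.e. forward expansion), and a three-epoch full bottleneck
(D, with T_ENDBOT < T_BOT enforced). Default search bounds: T_BOT in
[50, 1000] generations (wide because first-detection dates under-estimate
introduction dates), sizes in [1e2–1e3, 1e7] searched on a log10 scale,
G_R in [−1e-3, 1e-3] per generation.

## Expected SFS

In rescaled time τ = ∫dt/2N(t) the ancestral lineage-count process is the
standard coalescent death process with rates C(k,2). The package solves its
state probabilities once per sample size on a fixed τ grid (geometric, 3500
points to τ = 60, `deSolve::lsoda` at rtol 1e-10) and caches them; the
expected time with k lineages under any piecewise-exponential history is
then a single matrix–vector product of the cached trapezoid weights with
2N(t(τ)) evaluated on the grid. Expected branch lengths per frequency class
follow from the classical topology mixture C(K−i−1, k−2)/C(K−1, k−1)
(topology is independent of coalescence times), folded and normalized. On a
constant-size model this reproduces the closed-form 1/i spectrum to within
1e-8.

This analytic engine is the default for fitting because the composite
likelihood is then smooth and deterministic — exactly what a cyclic
one-dimensional Brent search needs. A Monte-Carlo engine
(`engine = "simulation"`, averaging per-class branch lengths over simulated
genealogies, 1e5 by default, with common random numbers per optimization
replicate) mirrors simulation-based workflows and is cross-checked against
the analytic engine in the tests.

## Simulator and ascertainment

`simulateSFS()` simulates coalescent genealogies by time rescaling
(piecewise-analytic integration of the pair intensity, including
exponential epochs) and drops a single mutation uniformly on the tree
length of each retained locus. One subtlety matters: real
single-SNP-per-locus datasets are *length-biased* — in the low-mutation
limit a locus segregates with probability proportional to its genealogy's
total length — so the marginal class probability of an ascertained SNP is
E[L_i]/E[L_total], not the per-genealogy ratio E[L_i/L_total]. The
simulator therefore accepts genealogies by rejection with probability
proportional to total length (bound = 4x a pilot mean, clipped at 1) before
placing the mutation. Without this the simulated spectra differ from the
likelihood's expectation by a few tenths of a percent per class, which is
enough to bias bottleneck-time estimates substantially along the soft
(N_ANC, T_BOT) likelihood ridge and degrade bootstrap coverage.

## Fitting, model choice, uncertainty

`fitModel()` maximizes the multinomial composite log-likelihood over
polymorphic folded classes (monomorphic class excluded and proportions
renormalized, since the data are SNPs; expected proportions floored at
1e-8). Each replicate starts uniformly (log-uniformly for sizes) inside the
bounds and runs up to 40 cycles of bounded Brent line searches, one free
parameter at a time, stopping early when a cycle gains < 1e-6 nats. AIC =
2k − 2 lnL in nats; a log10-based likelihood convention would differ by a
constant factor that cannot change rankings. `modelSelection()` reports
ΔAIC, Akaike weights, the fraction of replicate runs in which each model
attains the lowest AIC (the operationalisation of per-iteration selection
frequencies), and flags models within 3 units as jointly supported.
`parametricBootstrap()` re-simulates at the fitted values and refits from
them (fewer cycles suffice from a warm start), reporting percentile
intervals; replicates that fail are dropped, requiring 80% success.

## Study conditions and what they show

The recovery experiment fits model B to data simulated at T_BOT = 200
generations, N_ANC/N_CUR = 5, n = 30 diploids and 5,000 SNPs, with
N_CUR = 2,000 — a founder population of a few thousand. The contemporary
size was chosen from a noiseless identifiability profile: at this value the
composite likelihood is sharply curved in T_BOT, whereas for N_CUR in the
1e5 range the folded-SFS shape is nearly flat along the (N_ANC, T_BOT)
ridge and no method could localise T_BOT from 5,000 SNPs.
The desk-scale profile (4 random starts per fit, 50 bootstrap replicates,
20 repetitions; Monte-Carlo engine at 1e4 simulations where used) keeps the
whole experiment within a few minutes; published-scale settings
(100 replicates, 1e5 simulations, 100 bootstraps) are plain arguments.

The Tajima's D demonstration uses two generator scenarios: constant size
(D ≈ 0 within sampling error) and a severe founder event — about a dozen
founders growing exponentially to N_CUR = 1e5 over 1,500 generations
(G_R = −6e-3 backwards). Under length-biased ascertainment the founder
event must be severe enough that essentially no lineage survives into the
(large) ancestral epoch; otherwise the few loci that do retain deep
lineages carry disproportionate tree length, enrich intermediate
frequencies, and push D positive. This is a real property of
single-SNP-per-locus spectra, not an artifact.

# Host-plant use

`incidence()` and `compareIncidence()` cover the field summary: site-level
attacked/examined proportions are compared between species with a
quasibinomial (logit) GLM and an F test on the dispersion-scaled deviance
difference; complete separation is flagged. The Neu-method analysis maps
its two null hypotheses onto (1) an omnibus chi-square of attack counts
against availability proportions and (2) per-category Bonferroni
simultaneous t intervals on the attack shares,
p̂ ± t(α/2k, n−1)·√(p̂(1−p̂)/n), with n the total attacked plants at the
analysis level (taxon-level analyses pool across sites — the convention
adopted here since published analyses do not define n explicitly) and k the
number of simultaneous categories. Intervals are reported un-truncated —
small-use categories legitimately print negative lower bounds — with an
optional clamp. Classification: availability below the interval =
preference, inside = proportional use, above = avoidance. The per-category
step is meaningful when the omnibus test rejects; `neuAnalysis()` reports
the flag and classifies unconditionally for transparency.

# Niche overlap

`schoenersD()` (1 − ½Σ|p_a − p_b|) and `hellingersI()` (1 − ½Σ(√p_a −
√p_b)²) compare two habitat-suitability surfaces normalized to sum 1 over
valid cells. Grids must agree in shape and no-data mask; mismatches are an
error rather than a silent intersection, because a dropped cell changes
both normalizations. Hellinger's I dominates Schoener's D on any shared
support; the tests check 0 ≤ D ≤ I ≤ 1 empirically on random grids. Niche
model calibration itself (MaxEnt-style) is out of scope.

# Synthetic data: what it emulates, and what it does not

`simConfig()` defaults emulate a RAD-like SNP study of a recent invader:
20 diploids per population, 2,000 unlinked biallelic loci (one SNP each) on
one 2-Gbp pseudo-chromosome, 5% missing genotypes missing-completely-at-
random, N_CUR = 2e5 and a five-fold ancestral size ratio for bottleneck
scenarios. Two-deme differentiation uses the Balding–Nichols F-model
(ancestral frequencies Beta(0.5, 0.5); the F parameter is the recorded true
F_ST), so the island scenario tests the F_ST and clustering stages without
requiring a structured coalescent. Host surveys allocate attacks by
weighted sampling without replacement from the plant pool, and suitability
grids are Gaussian kernels mixed to an overlap target.

Passing tests on these generators show that the estimators recover the
structure the generators plant — neutral unlinked loci, random missingness,
no sequencing error, no linked selection, no spatial sampling artefacts.
They do not show robustness to the things real RAD data add: depth-
dependent genotyping error, allele dropout, batch effects, physical
linkage, or non-random missingness. Conclusions about real datasets still
require the usual diagnostic plots and sensitivity analyses.

# Numerical choices and limitations

- Missing data: pairwise-complete everywhere; admixture excludes missing
  entries from the loss; PCA mean-imputes.
- Composite likelihood flooring at 1e-8 with renormalization; likelihoods
  in nats.
- Brent line searches use an x-tolerance of 1e-4 of the (transformed)
  interval; size parameters are searched on log10 scale.
- The τ grid truncates at τ = 60, where residual mass is ~e-26; the grid
  is cached per sample size, as is the topology-mixture matrix.
- Model D's constraint T_ENDBOT < T_BOT is enforced by clipping each
  parameter's interval against the other's current value during the cycle.
- The composite likelihood treats SNPs as independent; with physically
  linked loci its curvature overstates information, so bootstrap rather
  than curvature-based intervals are used throughout.
- Weir–Cockerham theta is undefined when total variance components vanish
  (e.g. a completely monomorphic pair) and raises an error rather than
  returning 0.
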