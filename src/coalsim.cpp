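#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Piecewise-exponential (backwards-time) population size history.
// Epoch e covers [start[e], start[e+1]) with N(t) = size[e] * exp(growth[e]
// * (t - start[e])). The final epoch must have growth 0 so that total
// coalescent intensity is infinite.
struct SizeHistory {
  std::vector<double> start, size, growth;
  int nEpoch;
  SizeHistory(NumericVector s, NumericVector n, NumericVector g)
      : start(s.begin(), s.end()), size(n.begin(), n.end()),
        growth(g.begin(), g.end()), nEpoch(s.size()) {}

  // coalescent intensity integral for one pair: int_{t0}^{t1} ds / (2 N(s))
  double pairIntensity(int e, double t0, double t1) const {
    double g = growth[e], N0 = size[e], s0 = start[e];
    if (g == 0.0) return (t1 - t0) / (2.0 * N0);
    return (std::exp(-g * (t0 - s0)) - std::exp(-g * (t1 - s0))) /
           (2.0 * N0 * g);
  }

  // time > t0 within epoch e at which the pair intensity from t0 equals u
  double solveWithin(int e, double t0, double u) const {
    double g = growth[e], N0 = size[e], s0 = start[e];
    if (g == 0.0) return t0 + u * 2.0 * N0;
    double rhs = std::exp(-g * (t0 - s0)) - u * 2.0 * N0 * g;
    return s0 - std::log(rhs) / g;
  }

  // advance from time t with k lineages to the next coalescence time
  double nextCoalescence(double t, int k) const {
    double pairs = 0.5 * k * (k - 1);
    double need = R::exp_rand() / pairs;  // per-pair intensity still needed
    int e = nEpoch - 1;
    while (e > 0 && t < start[e]) --e;
    double cur = t;
    for (;;) {
      if (e + 1 < nEpoch) {
        double cap = pairIntensity(e, cur, start[e + 1]);
        if (need > cap) {
          need -= cap;
          cur = start[e + 1];
          ++e;
          continue;
        }
      }
      return solveWithin(e, cur, need);
    }
  }
};

static inline void drawPair(int k, int &a, int &b) {
  a = (int)(unif_rand() * k); if (a == k) a = k - 1;
  b = (int)(unif_rand() * (k - 1)); if (b == k - 1) b = k - 2;
  if (b >= a) ++b;
}

// One genealogy: fills classLen[i] (total branch length subtending i of the
// nCopies samples) and returns the total tree length.
static double simGenealogyClassLengths(const SizeHistory &hist, int nCopies,
                                       std::vector<int> &cnt,
                                       std::vector<double> &classLen) {
  int k = nCopies;
  double t = 0.0, total = 0.0;
  for (int i = 0; i < nCopies; ++i) cnt[i] = 1;
  std::fill(classLen.begin(), classLen.end(), 0.0);
  while (k > 1) {
    double tNext = hist.nextCoalescence(t, k);
    double dt = tNext - t;
    for (int i = 0; i < k; ++i) classLen[cnt[i]] += dt;
    total += k * dt;
    int a, b;
    drawPair(k, a, b);
    cnt[a] += cnt[b];
    cnt[b] = cnt[k - 1];
    --k;
    t = tNext;
  }
  return total;
}

// Length-biased acceptance bound: mean total tree length from a pilot run,
// scaled by 4 (acceptance probability L / bound, clipped at 1; the clipped
// tail mass is negligible for coalescent length distributions).
static double pilotLengthBound(const SizeHistory &hist, int nCopies) {
  std::vector<int> cnt(nCopies);
  std::vector<double> classLen(nCopies);
  double sum = 0.0;
  const int nPilot = 256;
  for (int i = 0; i < nPilot; ++i)
    sum += simGenealogyClassLengths(hist, nCopies, cnt, classLen);
  return 4.0 * sum / nPilot;
}

// Folded SFS of nSnps SNPs, one per locus. Loci are ascertained
// length-biased (a locus segregates with probability proportional to its
// total tree length in the low-mutation limit), then a single mutation is
// dropped uniformly on the tree. The resulting class counts are multinomial
// with probabilities E[L_i] / E[L_total].
// [[Rcpp::export(name = ".coalSimSFS")]]
IntegerVector coalSimSFS(int nCopies, NumericVector epochStart,
                         NumericVector epochSize, NumericVector epochGrowth,
                         int nSnps) {
  SizeHistory hist(epochStart, epochSize, epochGrowth);
  int half = nCopies / 2;
  IntegerVector out(half + 1);
  std::vector<int> cnt(nCopies);
  std::vector<double> classLen(nCopies);
  double bound = pilotLengthBound(hist, nCopies);

  int done = 0;
  while (done < nSnps) {
    double total = simGenealogyClassLengths(hist, nCopies, cnt, classLen);
    if (unif_rand() * bound > total) continue;  // length-biased ascertainment
    double u = unif_rand() * total;
    int derived = nCopies - 1;
    double acc = 0.0;
    for (int i = 1; i < nCopies; ++i) {
      acc += classLen[i];
      if (u <= acc) { derived = i; break; }
    }
    int folded = derived <= nCopies - derived ? derived : nCopies - derived;
    ++out[folded];
    ++done;
  }
  return out;
}

// Monte-Carlo expected branch length per unfolded frequency class
// (E[L_i], averaged over nSims genealogies), for the simulation-based
// likelihood engine.
// [[Rcpp::export(name = ".coalBranchLengths")]]
NumericVector coalBranchLengths(int nCopies, NumericVector epochStart,
                                NumericVector epochSize,
                                NumericVector epochGrowth, int nSims) {
  SizeHistory hist(epochStart, epochSize, epochGrowth);
  NumericVector out(nCopies);  // index i = class i, entry 0 unused
  std::vector<int> cnt(nCopies);
  std::vector<double> classLen(nCopies);
  for (int s = 0; s < nSims; ++s) {
    simGenealogyClassLengths(hist, nCopies, cnt, classLen);
    for (int i = 1; i < nCopies; ++i) out[i] += classLen[i];
  }
  for (int i = 1; i < nCopies; ++i) out[i] /= nSims;
  return out;
}

// Sample-resolved haplotypes: one SNP per length-bias-ascertained locus,
// derived alleles assigned to the descendants of a branch picked uniformly
// on tree length. Returns an nLoci x nCopies 0/1 matrix.
// [[Rcpp::export(name = ".coalSimHaplotypes")]]
IntegerMatrix coalSimHaplotypes(int nCopies, NumericVector epochStart,
                                NumericVector epochSize,
                                NumericVector epochGrowth, int nLoci) {
  SizeHistory hist(epochStart, epochSize, epochGrowth);
  int nNodes = 2 * nCopies - 1;
  IntegerMatrix out(nLoci, nCopies);
  std::vector<int> left(nNodes), right(nNodes), active(nCopies);
  std::vector<double> nodeTime(nNodes), blen(nNodes);
  double bound = pilotLengthBound(hist, nCopies);

  int done = 0;
  while (done < nLoci) {
    int k = nCopies;
    double t = 0.0, total = 0.0;
    for (int i = 0; i < nCopies; ++i) {
      active[i] = i;
      nodeTime[i] = 0.0;
    }
    int nextNode = nCopies;
    while (k > 1) {
      t = hist.nextCoalescence(t, k);
      int a, b;
      drawPair(k, a, b);
      int na = active[a], nb = active[b];
      left[nextNode] = na;
      right[nextNode] = nb;
      nodeTime[nextNode] = t;
      blen[na] = t - nodeTime[na];
      blen[nb] = t - nodeTime[nb];
      total += blen[na] + blen[nb];
      active[a] = nextNode;
      active[b] = active[k - 1];
      ++nextNode;
      --k;
    }
    if (unif_rand() * bound > total) continue;  // length-biased ascertainment
    int root = nextNode - 1;
    double u = unif_rand() * total, acc = 0.0;
    int hit = root - 1;
    for (int v = 0; v < root; ++v) {
      acc += blen[v];
      if (u <= acc) { hit = v; break; }
    }
    // mark descendants of the mutated branch
    std::vector<int> stack;
    stack.push_back(hit);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < nCopies) out(done, v) = 1;
      else {
        stack.push_back(left[v]);
        stack.push_back(right[v]);
      }
    }
    ++done;
  }
  return out;
}

// Pairwise (k = 2) coalescence times, for calibration tests.
// [[Rcpp::export(name = ".coalPairTimes")]]
NumericVector coalPairTimes(NumericVector epochStart, NumericVector epochSize,
                            NumericVector epochGrowth, int nRep) {
  SizeHistory hist(epochStart, epochSize, epochGrowth);
  NumericVector out(nRep);
  for (int i = 0; i < nRep; ++i) out[i] = hist.nextCoalescence(0.0, 2);
  return out;
}
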