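// Two-deme structured-coalescent simulator with piecewise-constant deme
// sizes, epoch-restricted backward migration, and a single merge event
// (deme 2 lineages move into deme 1 at tMerge, looking backward in time).
//
// Time is measured in generations, backward from the present (t = 0).
// Demography is a set of epochs [brk[e], brk[e+1]) with per-epoch diploid
// sizes N1, N2 and per-lineage backward migration rates m12 (deme 1 -> 2)
// and m21. Pair-coalescence rate within a deme of size N is
// k(k-1)/(4*N*ploidy) per generation (ploidy = 1 diploid autosomal,
// 0.5 haploid organellar).
//
// RNG is self-contained (splitmix64-seeded xorshift-style mt19937_64 with
// hand-rolled uniform/exponential/Poisson draws) so that results are
// deterministic for a given integer seed and independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(double seed) {
    s = static_cast<uint64_t>(seed);
    // scramble a couple of times so small seeds diverge immediately
    next();
    next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1)
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo(double rate) { return -std::log(unif()) / rate; }
  // integer in [0, n)
  int below(int n) { return static_cast<int>(unif() * n) % n; }
  // Poisson: Knuth for small mean, normal-rounding fallback for large
  int pois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 60.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    // Gaussian approximation with continuity correction (adequate for
    // the large-mean divergence draws this code makes)
    double u1 = unif(), u2 = unif();
    double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
    double x = lambda + std::sqrt(lambda) * z;
    return x < 0 ? 0 : static_cast<int>(x + 0.5);
  }
};

struct Genealogy {
  // nodes 0..n-1 are tips; internal nodes appended in coalescence order;
  // parent of root = -1
  std::vector<int> parent;
  std::vector<double> time;
  int n;
};

// simulate one genealogy; tips 0..n1-1 start in deme 1, n1..n1+n2-1 in deme 2
Genealogy simulate_genealogy(int n1, int n2,
                             const std::vector<double>& brk,
                             const std::vector<double>& N1,
                             const std::vector<double>& N2,
                             const std::vector<double>& m12,
                             const std::vector<double>& m21,
                             double tMerge, double ploidy, Rng& rng) {
  const int n = n1 + n2;
  Genealogy g;
  g.n = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);

  std::vector<int> act;           // active node ids
  std::vector<int> deme;          // deme of each active lineage (1 or 2)
  act.reserve(n); deme.reserve(n);
  for (int i = 0; i < n1; ++i) { act.push_back(i); deme.push_back(1); }
  for (int i = 0; i < n2; ++i) { act.push_back(n1 + i); deme.push_back(2); }

  double t = 0.0;
  size_t e = 0;
  const size_t nE = brk.size();
  int nextNode = n;
  bool merged = (tMerge <= 0.0);
  if (merged) for (size_t i = 0; i < deme.size(); ++i) deme[i] = 1;

  while (act.size() > 1) {
    int k1 = 0, k2 = 0;
    for (size_t i = 0; i < deme.size(); ++i) (deme[i] == 1 ? k1 : k2)++;
    double c1 = k1 > 1 ? k1 * (k1 - 1.0) / (4.0 * N1[e] * ploidy) : 0.0;
    double c2 = k2 > 1 ? k2 * (k2 - 1.0) / (4.0 * N2[e] * ploidy) : 0.0;
    double g12 = merged ? 0.0 : k1 * m12[e];
    double g21 = merged ? 0.0 : k2 * m21[e];
    double total = c1 + c2 + g12 + g21;
    double nextBrk = (e + 1 < nE) ? brk[e + 1] : R_PosInf;

    double dt = (total > 0.0) ? rng.expo(total) : R_PosInf;
    if (t + dt >= nextBrk) {
      if (!R_FINITE(nextBrk))
        stop("demography degenerate: no events possible and no further epochs");
      t = nextBrk;
      ++e;
      if (!merged && tMerge <= t) {
        for (size_t i = 0; i < deme.size(); ++i) deme[i] = 1;
        merged = true;
      }
      continue;
    }
    t += dt;
    double u = rng.unif() * total;
    if (u < c1 || u < c1 + c2) {
      int d = (u < c1) ? 1 : 2;
      // pick an unordered pair within deme d
      int kd = (d == 1) ? k1 : k2;
      int i1 = rng.below(kd), i2 = rng.below(kd - 1);
      if (i2 >= i1) ++i2;
      // map to positions among active lineages of deme d
      int seen = 0, p1 = -1, p2 = -1;
      for (size_t i = 0; i < deme.size(); ++i) {
        if (deme[i] == d) {
          if (seen == i1) p1 = static_cast<int>(i);
          if (seen == i2) p2 = static_cast<int>(i);
          ++seen;
        }
      }
      int node = nextNode++;
      g.parent[act[p1]] = node;
      g.parent[act[p2]] = node;
      g.time[node] = t;
      act[p1] = node;                    // replace first, drop second
      if (p2 != static_cast<int>(act.size()) - 1) {
        act[p2] = act.back();
        deme[p2] = deme.back();
      }
      act.pop_back();
      deme.pop_back();
    } else if (u < c1 + c2 + g12) {
      int pick = rng.below(k1), seen = 0;
      for (size_t i = 0; i < deme.size(); ++i)
        if (deme[i] == 1 && seen++ == pick) { deme[i] = 2; break; }
    } else {
      int pick = rng.below(k2), seen = 0;
      for (size_t i = 0; i < deme.size(); ++i)
        if (deme[i] == 2 && seen++ == pick) { deme[i] = 1; break; }
    }
  }
  return g;
}

void children_of(const Genealogy& g, std::vector<int>& c1, std::vector<int>& c2) {
  int m = static_cast<int>(g.parent.size());
  c1.assign(m, -1); c2.assign(m, -1);
  for (int i = 0; i < m - 1; ++i) {
    int p = g.parent[i];
    if (p >= 0) { if (c1[p] < 0) c1[p] = i; else c2[p] = i; }
  }
}

// per-node tip-descendant counts in each deme (tips assumed n1 then n2)
void descendant_counts(const Genealogy& g, int n1,
                       std::vector<int>& d1, std::vector<int>& d2) {
  int m = static_cast<int>(g.parent.size());
  d1.assign(m, 0); d2.assign(m, 0);
  for (int i = 0; i < g.n; ++i) (i < n1 ? d1[i] : d2[i]) = 1;
  // internal nodes are numbered in increasing time order, so a single
  // ascending pass accumulates children before parents
  for (int i = 0; i < m - 1; ++i) {
    int p = g.parent[i];
    if (p >= 0) { d1[p] += d1[i]; d2[p] += d2[i]; }
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(int n1, int n2, NumericVector brk, NumericVector N1,
                       NumericVector N2, NumericVector m12, NumericVector m21,
                       double tMerge, double ploidy, double seed) {
  Rng rng(seed);
  std::vector<double> b(brk.begin(), brk.end()), v1(N1.begin(), N1.end()),
      v2(N2.begin(), N2.end()), a(m12.begin(), m12.end()), c(m21.begin(), m21.end());
  if (n1 + n2 < 1) stop("need at least one sampled lineage");
  if (n1 + n2 == 1) {
    return List::create(_["parent"] = IntegerVector::create(NA_INTEGER),
                        _["time"] = NumericVector::create(0.0),
                        _["n"] = 1);
  }
  Genealogy g = simulate_genealogy(n1, n2, b, v1, v2, a, c, tMerge, ploidy, rng);
  IntegerVector parent(g.parent.size());
  for (size_t i = 0; i < g.parent.size(); ++i)
    parent[i] = g.parent[i] < 0 ? NA_INTEGER : g.parent[i] + 1; // 1-based for R
  return List::create(_["parent"] = parent,
                      _["time"] = NumericVector(g.time.begin(), g.time.end()),
                      _["n"] = g.n);
}

// Simulate one locus: genealogy + infinite-sites mutations at rate muL
// (per-generation mutation rate summed over the locus length). Returns a
// 0/1 matrix, rows = haplotypes (deme 1 tips first), cols = sites in
// arbitrary order (all sites are fully linked: no recombination).
// [[Rcpp::export(name = ".sim_locus_cpp")]]
IntegerMatrix sim_locus_cpp(int n1, int n2, NumericVector brk, NumericVector N1,
                            NumericVector N2, NumericVector m12, NumericVector m21,
                            double tMerge, double ploidy, double muL, double seed) {
  Rng rng(seed);
  std::vector<double> b(brk.begin(), brk.end()), v1(N1.begin(), N1.end()),
      v2(N2.begin(), N2.end()), a(m12.begin(), m12.end()), c(m21.begin(), m21.end());
  const int n = n1 + n2;
  if (n < 2) stop("need at least two sampled lineages");
  Genealogy g = simulate_genealogy(n1, n2, b, v1, v2, a, c, tMerge, ploidy, rng);

  std::vector<int> mutNode;
  for (int i = 0; i < 2 * n - 2; ++i) {
    double len = g.time[g.parent[i]] - g.time[i];
    int nm = rng.pois(muL * len);
    for (int k = 0; k < nm; ++k) mutNode.push_back(i);
  }
  int S = static_cast<int>(mutNode.size());
  IntegerMatrix out(n, S);
  std::vector<int> c1v, c2v;
  children_of(g, c1v, c2v);
  std::vector<int> stack;
  for (int s = 0; s < S; ++s) {
    stack.clear();
    stack.push_back(mutNode[s]);
    while (!stack.empty()) {
      int nd = stack.back(); stack.pop_back();
      if (nd < n) out(nd, s) = 1;
      else { stack.push_back(c1v[nd]); stack.push_back(c2v[nd]); }
    }
  }
  return out;
}

// Monte-Carlo expected joint SFS: accumulates muL * branch length into the
// (i, j) = (deme-1 descendants, deme-2 descendants) cell over nSims
// genealogies. Entries are expected SNP counts summed over simulations.
// [[Rcpp::export(name = ".sim_jsfs_cpp")]]
NumericMatrix sim_jsfs_cpp(int n1, int n2, NumericVector brk, NumericVector N1,
                           NumericVector N2, NumericVector m12, NumericVector m21,
                           double tMerge, double ploidy, double muL,
                           int nSims, double seed) {
  Rng rng(seed);
  std::vector<double> b(brk.begin(), brk.end()), v1(N1.begin(), N1.end()),
      v2(N2.begin(), N2.end()), a(m12.begin(), m12.end()), c(m21.begin(), m21.end());
  const int n = n1 + n2;
  if (n < 2) stop("need at least two sampled lineages");
  NumericMatrix acc(n1 + 1, n2 + 1);
  std::vector<int> d1, d2;
  for (int r = 0; r < nSims; ++r) {
    Genealogy g = simulate_genealogy(n1, n2, b, v1, v2, a, c, tMerge, ploidy, rng);
    descendant_counts(g, n1, d1, d2);
    for (int i = 0; i < 2 * n - 2; ++i) {
      double len = g.time[g.parent[i]] - g.time[i];
      acc(d1[i], d2[i]) += muL * len;
    }
  }
  return acc;
}

// Batch locus simulation for reference-table building: nLoci independent
// genealogies, returns a list of 0/1 matrices.
// [[Rcpp::export(name = ".sim_loci_cpp")]]
List sim_loci_cpp(int n1, int n2, NumericVector brk, NumericVector N1,
                  NumericVector N2, NumericVector m12, NumericVector m21,
                  double tMerge, double ploidy, NumericVector muL, double seed) {
  int nLoci = muL.size();
  List out(nLoci);
  for (int l = 0; l < nLoci; ++l) {
    out[l] = sim_locus_cpp(n1, n2, brk, N1, N2, m12, m21, tMerge, ploidy,
                           muL[l], seed + 1315423911.0 * (l + 1));
  }
  return out;
}
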