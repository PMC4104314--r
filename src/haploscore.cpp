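#include <Rcpp.h>
using namespace Rcpp;

// HaploScore DP over the four-haplotype-configuration DAG.
//
// A configuration at site l is a pair (i, j): haplotype i of individual a
// matched against haplotype j of individual b. Node weight is 0 when the two
// alleles agree (or either is missing), else 1/eps. The edge between
// consecutive configurations costs (number of changed coordinates)/sigma.
// Source and sink edges cost 0, so the initial configuration is free.
//
// Costs are carried as integer pairs (n_g, n_s) per DP cell; the real-valued
// score (n_g/eps + n_s/sigma)/|S| is formed only at the end. Two cells are
// compared via n_g*sigma + n_s*eps (the path cost scaled by eps*sigma > 0);
// exact ties are broken toward the smaller switch count n_s.

static const int HAMM[4][4] = {
  {0, 1, 1, 2},
  {1, 0, 2, 1},
  {1, 2, 0, 1},
  {2, 1, 1, 0}
};

static inline bool better(long g1, long s1, long g2, long s2,
                          double eps, double sigma) {
  double c1 = (double)g1 * sigma + (double)s1 * eps;
  double c2 = (double)g2 * sigma + (double)s2 * eps;
  if (c1 < c2) return true;
  if (c1 > c2) return false;
  return s1 < s2;
}

// Node mismatch indicator for configuration k = 2*i + j at segment-local
// site l. Missing alleles never witness a mismatch.
static inline int node_mismatch(const int* a1, const int* a2,
                                const int* b1, const int* b2,
                                int l, int k) {
  int av = (k < 2) ? a1[l] : a2[l];
  int bv = (k % 2 == 0) ? b1[l] : b2[l];
  if (av == NA_INTEGER || bv == NA_INTEGER) return 0;
  return av != bv ? 1 : 0;
}

struct DPResult {
  long n_g, n_s;
  long comparisons;
  bool above;      // early-terminated: score provably > max_score
  std::vector<int> path;
};

static DPResult run_dp(const int* a1, const int* a2,
                       const int* b1, const int* b2,
                       int L, double eps, double sigma,
                       double max_score, bool keep_path) {
  long G[4], S[4], Gn[4], Sn[4];
  long comparisons = 0;
  std::vector<unsigned char> bp;  // backpointers, L x 4
  if (keep_path) bp.assign((size_t)L * 4, 0);

  for (int k = 0; k < 4; ++k) {
    G[k] = node_mismatch(a1, a2, b1, b2, 0, k);
    S[k] = 0;
  }
  bool have_max = R_finite(max_score);
  DPResult res;
  res.above = false;

  for (int l = 1; l < L; ++l) {
    for (int k = 0; k < 4; ++k) {
      int m = node_mismatch(a1, a2, b1, b2, l, k);
      long bg = 0, bs = 0;
      int arg = -1;
      for (int p = 0; p < 4; ++p) {
        long cg = G[p];
        long cs = S[p] + HAMM[p][k];
        ++comparisons;  // one predecessor-state comparison
        if (arg < 0 || better(cg, cs, bg, bs, eps, sigma)) {
          bg = cg; bs = cs; arg = p;
        }
      }
      Gn[k] = bg + m;
      Sn[k] = bs;
      if (keep_path) bp[(size_t)l * 4 + k] = (unsigned char)arg;
    }
    for (int k = 0; k < 4; ++k) { G[k] = Gn[k]; S[k] = Sn[k]; }

    if (have_max) {
      // Weights are non-negative, so the best level cost is a lower bound on
      // the final path cost; once it exceeds max_score * L the segment is
      // provably above threshold.
      double lvl = R_PosInf;
      for (int k = 0; k < 4; ++k) {
        double c = (double)G[k] / eps + (double)S[k] / sigma;
        if (c < lvl) lvl = c;
      }
      if (lvl > max_score * (double)L) {
        res.n_g = -1; res.n_s = -1;
        res.comparisons = comparisons;
        res.above = true;
        return res;
      }
    }
  }

  int best = 0;
  for (int k = 1; k < 4; ++k) {
    if (better(G[k], S[k], G[best], S[best], eps, sigma)) best = k;
  }
  res.n_g = G[best];
  res.n_s = S[best];
  res.comparisons = comparisons;
  if (keep_path) {
    res.path.resize(L);
    int k = best;
    for (int l = L - 1; l >= 0; --l) {
      res.path[l] = k;
      if (l > 0) k = bp[(size_t)l * 4 + k];
    }
  }
  return res;
}

// [[Rcpp::export(name = ".haploscore_dp")]]
List haploscore_dp(IntegerVector a1, IntegerVector a2,
                   IntegerVector b1, IntegerVector b2,
                   double eps, double sigma,
                   double max_score = R_PosInf,
                   bool keep_path = false) {
  int L = a1.size();
  if (L < 1) stop("segment must contain at least one site");
  if (a2.size() != L || b1.size() != L || b2.size() != L)
    stop("haplotype vectors must have equal length");
  if (!R_finite(eps) || !R_finite(sigma) || eps <= 0 || sigma <= 0)
    stop("error rates must be finite and strictly positive");
  DPResult r = run_dp(a1.begin(), a2.begin(), b1.begin(), b2.begin(),
                      L, eps, sigma, max_score, keep_path);
  double score = r.above ? NA_REAL
                         : ((double)r.n_g / eps + (double)r.n_s / sigma) / L;
  List out = List::create(
    _["haploscore"] = score,
    _["n_g"] = r.above ? NA_INTEGER : (int)r.n_g,
    _["n_s"] = r.above ? NA_INTEGER : (int)r.n_s,
    _["n_sites"] = L,
    _["comparisons"] = (double)r.comparisons,
    _["above_threshold"] = r.above);
  if (keep_path && !r.above) out["path"] = IntegerVector(r.path.begin(), r.path.end());
  return out;
}

// [[Rcpp::export(name = ".haploscore_batch")]]
DataFrame haploscore_batch_cpp(IntegerMatrix hap1, IntegerMatrix hap2,
                               IntegerVector ia, IntegerVector ib,
                               IntegerVector start, IntegerVector end,
                               double eps, double sigma,
                               double max_score) {
  int n = ia.size();
  if (!R_finite(eps) || !R_finite(sigma) || eps <= 0 || sigma <= 0)
    stop("error rates must be finite and strictly positive");
  NumericVector score(n);
  IntegerVector ng(n), ns(n);
  LogicalVector above(n);
  for (int q = 0; q < n; ++q) {
    int s0 = start[q] - 1, s1 = end[q] - 1;
    int L = s1 - s0 + 1;
    if (s0 < 0 || s1 >= hap1.nrow() || L < 1)
      stop("segment %d has invalid site interval", q + 1);
    int ca = ia[q] - 1, cb = ib[q] - 1;
    DPResult r = run_dp(&hap1(s0, ca), &hap2(s0, ca),
                        &hap1(s0, cb), &hap2(s0, cb),
                        L, eps, sigma, max_score, false);
    if (r.above) {
      score[q] = NA_REAL; ng[q] = NA_INTEGER; ns[q] = NA_INTEGER;
      above[q] = true;
    } else {
      score[q] = ((double)r.n_g / eps + (double)r.n_s / sigma) / L;
      ng[q] = (int)r.n_g; ns[q] = (int)r.n_s;
      above[q] = false;
    }
  }
  return DataFrame::create(_["haploscore"] = score, _["n_g"] = ng,
                           _["n_s"] = ns, _["above_threshold"] = above);
}

// Exhaustive oracle: enumerates every one of the 4^L configuration sequences
// by depth-first search, accumulating node and edge error counts directly
// from the allele vectors. Shares no cost bookkeeping with the DP above; used
// to verify it.
//
// [[Rcpp::export(name = ".haploscore_bruteforce")]]
List haploscore_bruteforce_cpp(IntegerVector a1, IntegerVector a2,
                               IntegerVector b1, IntegerVector b2,
                               double eps, double sigma, int max_sites = 10) {
  int L = a1.size();
  if (L < 1) stop("segment must contain at least one site");
  if (L > max_sites)
    stop("brute-force oracle limited to %d sites (got %d)", max_sites, L);
  if (!R_finite(eps) || !R_finite(sigma) || eps <= 0 || sigma <= 0)
    stop("error rates must be finite and strictly positive");

  // mismatch table recomputed here, independently of run_dp's helper
  std::vector<int> mm((size_t)L * 4);
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < 2; ++i) {
      for (int j = 0; j < 2; ++j) {
        int av = i == 0 ? a1[l] : a2[l];
        int bv = j == 0 ? b1[l] : b2[l];
        int m = (av == NA_INTEGER || bv == NA_INTEGER) ? 0 : (av != bv ? 1 : 0);
        mm[(size_t)l * 4 + (i * 2 + j)] = m;
      }
    }
  }

  long best_g = -1, best_s = -1;
  std::vector<int> state(L), best_path(L);

  // iterative DFS over configuration sequences
  std::vector<int> lg(L + 1, 0), ls(L + 1, 0);
  int l = 0;
  state[0] = -1;
  while (l >= 0) {
    if (++state[l] > 3) { --l; continue; }
    int k = state[l];
    int sw = (l == 0) ? 0 : ((state[l - 1] ^ k) == 3 ? 2
                             : (state[l - 1] == k ? 0 : 1));
    lg[l + 1] = lg[l] + mm[(size_t)l * 4 + k];
    ls[l + 1] = ls[l] + sw;
    if (l == L - 1) {
      long g = lg[L], s = ls[L];
      bool take;
      if (best_g < 0) {
        take = true;
      } else {
        double c = (double)g * sigma + (double)s * eps;
        double cb = (double)best_g * sigma + (double)best_s * eps;
        take = (c < cb) || (c == cb && s < best_s);
      }
      if (take) { best_g = g; best_s = s; best_path = state; }
    } else {
      ++l;
      state[l] = -1;
    }
  }

  double score = ((double)best_g / eps + (double)best_s / sigma) / L;
  return List::create(
    _["haploscore"] = score,
    _["n_g"] = (int)best_g,
    _["n_s"] = (int)best_s,
    _["n_sites"] = L,
    _["path"] = IntegerVector(best_path.begin(), best_path.end()));
}
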