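#include <Rcpp.h>
using namespace Rcpp;

// Permissive diplotype seed-and-extend candidate detector, emulating the
// GERMLINE configuration (-bits W -err_hom E -err_het 0 -w_extend):
//   1. seeds: consecutive non-overlapping W-site windows in which some
//      haplotype pair (one haplotype from each individual) matches exactly
//      (missing alleles match anything);
//   2. maximal runs of seed windows are extended site-by-site in both
//      directions through any site that is not an opposite homozygote,
//      with a total budget of E opposite homozygotes per match;
//   3. overlapping matches are merged, ends are trimmed so that a reported
//      segment never starts or ends on an opposite-homozygote site.
// Genetic-length filtering (min_cM) is applied by the R wrapper.

static inline bool allele_match(int a, int b) {
  return a == NA_INTEGER || b == NA_INTEGER || a == b;
}

static inline bool is_opp_hom(const int* a1, const int* a2,
                              const int* b1, const int* b2, int s) {
  int x1 = a1[s], x2 = a2[s], y1 = b1[s], y2 = b2[s];
  if (x1 == NA_INTEGER || x2 == NA_INTEGER ||
      y1 == NA_INTEGER || y2 == NA_INTEGER) return false;
  return x1 == x2 && y1 == y2 && x1 != y1;
}

// [[Rcpp::export(name = ".detect_candidates")]]
DataFrame detect_candidates_cpp(IntegerMatrix hap1, IntegerMatrix hap2,
                                IntegerVector ia, IntegerVector ib,
                                int window_sites, int max_hom_err) {
  int n_sites = hap1.nrow();
  int n_windows = n_sites / window_sites;
  std::vector<int> out_pair, out_start, out_end;
  std::vector<unsigned char> seed(n_windows);

  for (int q = 0; q < ia.size(); ++q) {
    int ca = ia[q] - 1, cb = ib[q] - 1;
    const int* a1 = &hap1(0, ca);
    const int* a2 = &hap2(0, ca);
    const int* b1 = &hap1(0, cb);
    const int* b2 = &hap2(0, cb);

    bool any_seed = false;
    for (int w = 0; w < n_windows; ++w) {
      int s0 = w * window_sites, s1 = s0 + window_sites;
      bool hit = false;
      for (int hp = 0; hp < 4 && !hit; ++hp) {
        const int* ha = (hp < 2) ? a1 : a2;
        const int* hb = (hp % 2 == 0) ? b1 : b2;
        bool ok = true;
        for (int s = s0; s < s1; ++s) {
          if (!allele_match(ha[s], hb[s])) { ok = false; break; }
        }
        hit = ok;
      }
      seed[w] = hit;
      any_seed = any_seed || hit;
    }
    if (!any_seed) continue;

    // extend maximal seed-window runs
    std::vector<std::pair<int, int> > matches;
    int w = 0;
    while (w < n_windows) {
      if (!seed[w]) { ++w; continue; }
      int w0 = w;
      while (w < n_windows && seed[w]) ++w;
      int lo = w0 * window_sites;          // inclusive
      int hi = w * window_sites - 1;       // inclusive
      int budget = max_hom_err;
      // alternate right/left extension so the shared budget is spent evenly
      int r = hi + 1, l = lo - 1;
      bool r_open = true, l_open = true;
      while (r_open || l_open) {
        if (r_open) {
          if (r >= n_sites) { r_open = false; }
          else {
            bool oh = is_opp_hom(a1, a2, b1, b2, r);
            if (oh && budget == 0) r_open = false;
            else { if (oh) --budget; hi = r; ++r; }
          }
        }
        if (l_open) {
          if (l < 0) { l_open = false; }
          else {
            bool oh = is_opp_hom(a1, a2, b1, b2, l);
            if (oh && budget == 0) l_open = false;
            else { if (oh) --budget; lo = l; --l; }
          }
        }
      }
      // trim terminal opposite homozygotes
      while (lo < hi && is_opp_hom(a1, a2, b1, b2, lo)) ++lo;
      while (hi > lo && is_opp_hom(a1, a2, b1, b2, hi)) --hi;
      matches.push_back(std::make_pair(lo, hi));
    }

    // merge overlapping matches
    size_t k = 0;
    for (size_t m = 1; m < matches.size(); ++m) {
      if (matches[m].first <= matches[k].second + 1) {
        if (matches[m].second > matches[k].second)
          matches[k].second = matches[m].second;
      } else {
        matches[++k] = matches[m];
      }
    }
    matches.resize(k + 1);

    for (size_t m = 0; m < matches.size(); ++m) {
      out_pair.push_back(q + 1);
      out_start.push_back(matches[m].first + 1);
      out_end.push_back(matches[m].second + 1);
    }
  }

  return DataFrame::create(
    _["pair"] = IntegerVector(out_pair.begin(), out_pair.end()),
    _["site_start"] = IntegerVector(out_start.begin(), out_start.end()),
    _["site_end"] = IntegerVector(out_end.begin(), out_end.end()));
}
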