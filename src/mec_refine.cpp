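#include <Rcpp.h>
using namespace Rcpp;

// Exact-MEC polishing and confidence margins for one connected component.
//
// Fragments are given in CSR form over local member ranks (position order):
// fragment f covers obs indices frag_ptr[f] .. frag_ptr[f+1]-1, with
// obs_rank (0-based member rank) and obs_allele (0/1). h is the phase bit
// per member. The MEC cost of fragment f is min(m_f, k_f - m_f) where
// m_f = #obs with allele != h[rank].
//
// The routine repeatedly applies the best single-member or contiguous-run
// flip (runs up to max_seg members) that lowers the exact MEC, then, at
// the optimum, marks every run whose flip would change the MEC by less
// than `min_margin` — members whose phase rests on fewer than min_margin
// observations of evidence. Returns the polished phase, the pruned flags
// and the final MEC.
//
// [[Rcpp::export]]
List mec_refine(IntegerVector frag_ptr, IntegerVector obs_rank,
                IntegerVector obs_allele, IntegerVector h_init,
                IntegerVector var_ptr, IntegerVector var_frag,
                IntegerVector var_obs, int max_seg, double min_margin,
                bool do_prune) {
  int n = h_init.size();
  int nfrag = frag_ptr.size() - 1;
  std::vector<int> h(h_init.begin(), h_init.end());
  std::vector<int> m(nfrag, 0), k(nfrag, 0);
  for (int f = 0; f < nfrag; ++f) {
    for (int t = frag_ptr[f]; t < frag_ptr[f + 1]; ++t) {
      k[f]++;
      if (obs_allele[t] != h[obs_rank[t]]) m[f]++;
    }
  }
  auto cost = [&](int mm, int kk) { return mm < kk - mm ? mm : kk - mm; };

  // scratch for per-fragment mismatch deltas of a candidate window flip
  std::vector<int> dm(nfrag, 0);
  std::vector<int> touched;
  touched.reserve(64);

  // delta MEC of flipping members [a, b] (inclusive ranks)
  auto window_delta = [&](int a, int b) {
    touched.clear();
    for (int r = a; r <= b; ++r) {
      for (int t = var_ptr[r]; t < var_ptr[r + 1]; ++t) {
        int f = var_frag[t];
        if (dm[f] == 0) touched.push_back(f);
        int x = (obs_allele[var_obs[t]] != h[r]) ? 1 : 0;
        dm[f] += 1 - 2 * x;
      }
    }
    double d = 0.0;
    for (int f : touched) {
      d += cost(m[f] + dm[f], k[f]) - cost(m[f], k[f]);
      dm[f] = 0;
    }
    return d;
  };

  auto commit = [&](int a, int b) {
    for (int r = a; r <= b; ++r) {
      for (int t = var_ptr[r]; t < var_ptr[r + 1]; ++t) {
        int f = var_frag[t];
        int x = (obs_allele[var_obs[t]] != h[r]) ? 1 : 0;
        m[f] += 1 - 2 * x;
      }
      h[r] = 1 - h[r];
    }
  };

  int max_rounds = 4 * n + 16;
  for (int round = 0; round < max_rounds; ++round) {
    bool improved = false;
    for (int L = 1; L <= max_seg && L < n; ++L) {
      for (int a = 0; a + L <= n; ++a) {
        double d = window_delta(a, a + L - 1);
        if (d < -1e-9) {
          commit(a, a + L - 1);
          improved = true;
        }
      }
    }
    if (!improved) break;
  }

  LogicalVector pruned(n, false);
  if (do_prune) {
    // L == n would be the global flip (margin always 0); never pruned
    for (int L = 1; L <= max_seg && L < n; ++L) {
      for (int a = 0; a + L <= n; ++a) {
        double d = window_delta(a, a + L - 1);
        if (d < min_margin) {
          for (int r = a; r < a + L; ++r) pruned[r] = true;
        }
      }
    }
  }

  long long mec = 0;
  for (int f = 0; f < nfrag; ++f) mec += cost(m[f], k[f]);
  return List::create(_["h"] = IntegerVector(h.begin(), h.end()),
                      _["pruned"] = pruned,
                      _["mec"] = (double)mec);
}
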