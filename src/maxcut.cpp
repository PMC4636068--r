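#include <Rcpp.h>
using namespace Rcpp;

// Best-improvement local search for weighted max-cut style phasing.
//
// The variant graph is given in CSR form: for node i (0-based), its
// neighbours are adj_idx[adj_ptr[i] .. adj_ptr[i+1]-1] with signed weights
// adj_w (positive = fragment votes say "same phase", negative = "opposite
// phase"). Spins s[i] in {-1,+1} encode the phase; the objective is
// sum_{i<j} w_ij * s_i * s_j, maximised by repeatedly flipping the single
// spin with the largest positive gain until no flip improves. Gains are
// maintained incrementally, so each flip costs O(degree).
//
// [[Rcpp::export]]
IntegerVector maxcut_local_search(IntegerVector adj_ptr,
                                 IntegerVector adj_idx,
                                 NumericVector adj_w,
                                 IntegerVector s_init,
                                 int max_iters) {
  int n = s_init.size();
  std::vector<int> s(s_init.begin(), s_init.end());
  // field[i] = sum_j w_ij * s_j
  std::vector<double> field(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k)
      field[i] += adj_w[k] * s[adj_idx[k]];

  long long max_flips = (long long)max_iters * (n > 0 ? n : 1);
  for (long long it = 0; it < max_flips; ++it) {
    // gain of flipping i: -2 * s_i * field_i
    int best = -1;
    double best_gain = 1e-12;  // strictly positive gains only
    for (int i = 0; i < n; ++i) {
      double g = -2.0 * s[i] * field[i];
      if (g > best_gain) { best_gain = g; best = i; }
    }
    if (best < 0) break;
    s[best] = -s[best];
    double delta = 2.0 * s[best];
    for (int k = adj_ptr[best]; k < adj_ptr[best + 1]; ++k)
      field[adj_idx[k]] += delta * adj_w[k];
  }
  return IntegerVector(s.begin(), s.end());
}
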