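// Spike renderer: fills a timeslots x inputs binary matrix where cell
// (t, i) spikes with the exact chance-draw probability
//   P = clamp(ceil(propensity * factor) - 1, 0, 10000) / 10000
// using R's RNG stream (one uniform draw per cell, in row-major slot
// order), so renderings are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix render_spikes_cpp(NumericMatrix prob, // n_active_rows x n_inputs
                                IntegerVector row_of_slot) { // per slot, 1-based
  const int n_slots = row_of_slot.size();
  const int n_inputs = prob.ncol();
  IntegerMatrix spikes(n_slots, n_inputs);
  std::vector<double> p((size_t)n_slots * n_inputs);
  for (int t = 0; t < n_slots; ++t) {
    const int r = row_of_slot[t] - 1;
    for (int i = 0; i < n_inputs; ++i)
      p[(size_t)t + (size_t)i * n_slots] = prob(r, i);
  }
  RNGScope scope;
  int *out = spikes.begin();
  const size_t n = p.size();
  for (size_t k = 0; k < n; ++k)
    out[k] = unif_rand() < p[k] ? 1 : 0;
  return spikes;
}
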