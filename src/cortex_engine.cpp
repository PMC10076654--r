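// Fast window engine for the columnar cortex.
//
// Runs one full presentation window (all timeslots) with the same dynamics
// as the R reference engine in cortex.R: two-stage integration per timeslot
// (branch potential, then count of firing branches), one-timeslot
// transmission delay between layers, within-window plasticity bookkeeping
// (input-before-fire pairings, contribution misses, firing counts) and the
// end-of-window plasticity rules (potentiate-if-paired-enough with implicit
// reversal, contribution-miss depression, homeostatic proportional scaling).
//
// Weights are constant within the window and all changes apply at window
// end, so the engine can defer the pairing / contribution-miss counts:
// per-slot it only records firing bitmasks (one bit per timeslot for every
// input, branch and neuron), and at window end recovers for every synapse
//   pair_count = popcount(neuron_fire_mask & (input_mask | input_mask << 1))
//   miss_count = popcount(branch_fire_mask & ~input_mask)
// which avoids touching every synapse of a firing neuron at every timeslot.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

typedef std::vector<uint64_t> BitRows; // rows x n_words, row-major

inline void set_bit(BitRows &m, int n_words, int row, int t) {
  m[(size_t)row * n_words + (t >> 6)] |= (uint64_t)1 << (t & 63);
}

// out = in | (in << 1) per row (bit t set if bit t or t-1 set in `in`)
void or_shift1(const BitRows &in, BitRows &out, int n_rows, int n_words) {
  for (int r = 0; r < n_rows; ++r) {
    const uint64_t *a = &in[(size_t)r * n_words];
    uint64_t *b = &out[(size_t)r * n_words];
    uint64_t carry = 0;
    for (int wd = 0; wd < n_words; ++wd) {
      b[wd] = a[wd] | (a[wd] << 1) | carry;
      carry = a[wd] >> 63;
    }
  }
}

// shift every row left by one bit (value at t moves to t+1)
void shift1(const BitRows &in, BitRows &out, int n_rows, int n_words) {
  for (int r = 0; r < n_rows; ++r) {
    const uint64_t *a = &in[(size_t)r * n_words];
    uint64_t *b = &out[(size_t)r * n_words];
    uint64_t carry = 0;
    for (int wd = 0; wd < n_words; ++wd) {
      b[wd] = (a[wd] << 1) | carry;
      carry = a[wd] >> 63;
    }
  }
}

inline int pop_and(const uint64_t *a, const uint64_t *b, int n_words) {
  int c = 0;
  for (int wd = 0; wd < n_words; ++wd)
    c += __builtin_popcountll(a[wd] & b[wd]);
  return c;
}

inline int pop_andnot(const uint64_t *a, const uint64_t *b, int n_words) {
  int c = 0;
  for (int wd = 0; wd < n_words; ++wd)
    c += __builtin_popcountll(a[wd] & ~b[wd]);
  return c;
}

struct Layer {
  int n_neurons, n_branches, n_syn, syn_per_neuron, n_branch_total;
  double theta_b;
  int theta_n;
  std::vector<int> src;      // 0-based source index per synapse
  std::vector<double> w;
  std::vector<int> fires;    // per-neuron window firing count
  BitRows bfire, nfire;      // per-branch / per-neuron firing bitmasks
};

void init_layer(Layer &L, int n_neurons, int n_branches, int n_syn,
                double theta_b, int theta_n,
                const IntegerVector &src1based, const NumericVector &wgt,
                int n_words) {
  L.n_neurons = n_neurons;
  L.n_branches = n_branches;
  L.n_syn = n_syn;
  L.syn_per_neuron = n_branches * n_syn;
  L.n_branch_total = n_neurons * n_branches;
  L.theta_b = theta_b;
  L.theta_n = theta_n;
  const R_xlen_t n = src1based.size();
  L.src.resize(n);
  L.w.resize(n);
  for (R_xlen_t s = 0; s < n; ++s) {
    L.src[s] = src1based[s] - 1;
    L.w[s] = wgt[s];
  }
  L.fires.assign(n_neurons, 0);
  L.bfire.assign((size_t)L.n_branch_total * n_words, 0);
  L.nfire.assign((size_t)n_neurons * n_words, 0);
}

// one integration slot for layers 2-3 (few synapses; direct gather)
void step_small_layer(Layer &L, int t, int n_words,
                      const std::vector<uint8_t> &x_now,
                      std::vector<uint8_t> &y_now) {
  for (int n = 0; n < L.n_neurons; ++n) {
    const int base = n * L.syn_per_neuron;
    int fired_branches = 0;
    for (int b = 0; b < L.n_branches; ++b) {
      const int b0 = base + b * L.n_syn;
      double pot = 0.0;
      for (int s = b0; s < b0 + L.n_syn; ++s)
        if (x_now[L.src[s]]) pot += L.w[s];
      if (pot >= L.theta_b) {
        ++fired_branches;
        set_bit(L.bfire, n_words, n * L.n_branches + b, t);
      }
    }
    if (fired_branches >= L.theta_n) {
      y_now[n] = 1;
      ++L.fires[n];
      set_bit(L.nfire, n_words, n, t);
    } else {
      y_now[n] = 0;
    }
  }
}

// end-of-window plasticity from the firing bitmasks.
// in_mask:  per source row, input activity at the layer's integration slot
// pair_in:  in_mask | (in_mask << 1)  (input at the fire slot or one before)
void end_window(Layer &L, const BitRows &in_mask, const BitRows &pair_in,
                int n_words, double d_pot, double d_dep, int pair_min,
                int m_miss, int rho_max, double s_homeo, double w_max) {
  const size_t n = L.w.size();
  for (size_t s = 0; s < n; ++s) {
    const int neuron = (int)(s / L.syn_per_neuron);
    const int branch = (int)(s / L.n_syn);
    const uint64_t *in_row = &in_mask[(size_t)L.src[s] * n_words];
    const uint64_t *pair_row = &pair_in[(size_t)L.src[s] * n_words];
    double w = L.w[s];
    if (pop_and(&L.nfire[(size_t)neuron * n_words], pair_row,
                n_words) >= pair_min) {
      w += d_pot;
      if (w > w_max) w = w_max;
    }
    if (pop_andnot(&L.bfire[(size_t)branch * n_words], in_row,
                   n_words) >= m_miss) {
      w -= d_dep;
      if (w < 0.0) w = 0.0;
    }
    L.w[s] = w;
  }
  for (int ni = 0; ni < L.n_neurons; ++ni) {
    if (L.fires[ni] > rho_max) {
      const int base = ni * L.syn_per_neuron;
      for (int s = base; s < base + L.syn_per_neuron; ++s)
        L.w[s] *= s_homeo;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List cortex_window_cpp(int n_columns, int n_inputs,
                       IntegerVector neurons, IntegerVector branches,
                       IntegerVector syn_per_branch,
                       NumericVector theta_branch, IntegerVector theta_neuron,
                       NumericVector d_pot, NumericVector d_dep,
                       int pair_min, IntegerVector m_miss,
                       IntegerVector rho_max, NumericVector s_homeo,
                       NumericVector w_max,
                       List src, List w,
                       IntegerMatrix spikes_t,  // n_inputs x n_slots
                       IntegerVector segments, int n_seg, bool record) {
  const int n_slots = spikes_t.ncol();
  if (spikes_t.nrow() != n_inputs)
    stop("spike matrix height does not match input count");
  const int n_words = (n_slots + 63) / 64;

  Layer L1, L2, L3;
  init_layer(L1, neurons[0] * n_columns, branches[0], syn_per_branch[0],
             theta_branch[0], theta_neuron[0], src[0], w[0], n_words);
  init_layer(L2, neurons[1] * n_columns, branches[1], syn_per_branch[1],
             theta_branch[1], theta_neuron[1], src[1], w[1], n_words);
  init_layer(L3, neurons[2] * n_columns, branches[2], syn_per_branch[2],
             theta_branch[2], theta_neuron[2], src[2], w[2], n_words);

  // input-major layout of layer-1 synapses (CSR): per input, a contiguous
  // run of (weight, branch) pairs, so active-input accumulation streams
  const size_t nsyn1 = L1.src.size();
  std::vector<int> inv_ptr(n_inputs + 1, 0);
  for (size_t s = 0; s < nsyn1; ++s) ++inv_ptr[L1.src[s] + 1];
  for (int i = 0; i < n_inputs; ++i) inv_ptr[i + 1] += inv_ptr[i];
  std::vector<int> inv_branch(nsyn1);
  std::vector<double> inv_w(nsyn1);
  {
    std::vector<int> cur(inv_ptr.begin(), inv_ptr.end() - 1);
    for (size_t s = 0; s < nsyn1; ++s) {
      const int at = cur[L1.src[s]]++;
      inv_branch[at] = (int)(s / L1.n_syn);
      inv_w[at] = L1.w[s];
    }
  }
  std::vector<double> pot1((size_t)L1.n_branch_total);

  BitRows act((size_t)n_inputs * n_words, 0);
  std::vector<uint8_t> y1_now(L1.n_neurons, 0), y1_p1(L1.n_neurons, 0);
  std::vector<uint8_t> y2_now(L2.n_neurons, 0), y2_p1(L2.n_neurons, 0);
  std::vector<uint8_t> y3_now(L3.n_neurons, 0);
  std::vector<int> active;
  active.reserve(n_inputs);

  std::vector<int> counts_v((size_t)n_columns * n_seg, 0);
  IntegerMatrix r1, r2, r3;
  if (record) {
    r1 = IntegerMatrix(n_slots, L1.n_neurons);
    r2 = IntegerMatrix(n_slots, L2.n_neurons);
    r3 = IntegerMatrix(n_slots, L3.n_neurons);
  }
  const int neurons3_per_col = neurons[2];

  for (int t = 0; t < n_slots; ++t) {
    const int *xcol = &spikes_t(0, t);
    active.clear();
    for (int i = 0; i < n_inputs; ++i)
      if (xcol[i]) {
        active.push_back(i);
        set_bit(act, n_words, i, t);
      }

    // layer 1: streaming accumulation over active inputs
    std::fill(pot1.begin(), pot1.end(), 0.0);
    for (size_t ai = 0; ai < active.size(); ++ai) {
      const int i = active[ai];
      const int k1 = inv_ptr[i + 1];
      for (int k = inv_ptr[i]; k < k1; ++k)
        pot1[inv_branch[k]] += inv_w[k];
    }
    for (int n = 0; n < L1.n_neurons; ++n) {
      const int b0 = n * L1.n_branches;
      int fired_branches = 0;
      for (int b = 0; b < L1.n_branches; ++b) {
        if (pot1[b0 + b] >= L1.theta_b) {
          ++fired_branches;
          set_bit(L1.bfire, n_words, b0 + b, t);
        }
      }
      if (fired_branches >= L1.theta_n) {
        y1_now[n] = 1;
        ++L1.fires[n];
        set_bit(L1.nfire, n_words, n, t);
      } else {
        y1_now[n] = 0;
      }
    }

    // layers 2-3 integrate the previous slot's fires
    step_small_layer(L2, t, n_words, y1_p1, y2_now);
    step_small_layer(L3, t, n_words, y2_p1, y3_now);

    const int seg = segments[t >= 2 ? t - 2 : 0] - 1;
    for (int n = 0; n < L3.n_neurons; ++n)
      if (y3_now[n])
        ++counts_v[(size_t)seg * n_columns + (n / neurons3_per_col)];

    if (record) {
      for (int n = 0; n < L1.n_neurons; ++n) r1(t, n) = y1_now[n];
      for (int n = 0; n < L2.n_neurons; ++n) r2(t, n) = y2_now[n];
      for (int n = 0; n < L3.n_neurons; ++n) r3(t, n) = y3_now[n];
    }

    std::swap(y1_p1, y1_now);
    std::swap(y2_p1, y2_now);
  }

  // input-activity masks at each layer's integration slot: layer 1 sees the
  // external inputs directly; layers 2-3 see the previous layer's fires
  // delayed by one slot
  BitRows in2((size_t)L1.n_neurons * n_words, 0);
  BitRows in3((size_t)L2.n_neurons * n_words, 0);
  shift1(L1.nfire, in2, L1.n_neurons, n_words);
  shift1(L2.nfire, in3, L2.n_neurons, n_words);
  BitRows pair1((size_t)n_inputs * n_words, 0);
  BitRows pair2((size_t)L1.n_neurons * n_words, 0);
  BitRows pair3((size_t)L2.n_neurons * n_words, 0);
  or_shift1(act, pair1, n_inputs, n_words);
  or_shift1(in2, pair2, L1.n_neurons, n_words);
  or_shift1(in3, pair3, L2.n_neurons, n_words);

  end_window(L1, act, pair1, n_words, d_pot[0], d_dep[0], pair_min,
             m_miss[0], rho_max[0], s_homeo[0], w_max[0]);
  end_window(L2, in2, pair2, n_words, d_pot[1], d_dep[1], pair_min,
             m_miss[1], rho_max[1], s_homeo[1], w_max[1]);
  end_window(L3, in3, pair3, n_words, d_pot[2], d_dep[2], pair_min,
             m_miss[2], rho_max[2], s_homeo[2], w_max[2]);

  IntegerMatrix counts(n_columns, n_seg);
  std::copy(counts_v.begin(), counts_v.end(), counts.begin());
  // hold each fresh allocation in an Rcpp object before List::create:
  // create() itself allocates and can trigger GC, which would collect
  // unprotected wrap() temporaries
  NumericVector w1 = wrap(L1.w), w2 = wrap(L2.w), w3 = wrap(L3.w);
  List wout = List::create(w1, w2, w3);
  IntegerVector f1 = wrap(L1.fires), f2 = wrap(L2.fires), f3 = wrap(L3.fires);
  List fires = List::create(f1, f2, f3);
  List out = List::create(Named("w") = wout, Named("counts") = counts,
                          Named("fires") = fires);
  if (record)
    out["rasters"] = List::create(r1, r2, r3);
  return out;
}
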