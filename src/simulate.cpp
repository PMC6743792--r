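#include <Rcpp.h>
using namespace Rcpp;

// Ensemble Boolean-network simulation.
//
// Rules are pre-compiled to per-node truth tables: node j has k[j]
// regulators (0 = hold its own state), regulator indices in regs(j, 0..2)
// (1-based, 0 when unused) and an 8-entry lookup table tt(j, .) indexed by
// the regulator bit pattern b1 + 2*b2 + 4*b3. Clamped nodes (clamp[j] >= 0)
// are pinned to their clamp value at every step including t = 0.
//
// For each sample (column of init) the initial bit of node j is a
// Bernoulli(init(j, col)) draw; `runs` trajectories of `steps` synchronous
// (or asynchronous random-order) updates are averaged over the last `tail`
// steps. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericMatrix simulate_ensemble_cpp(IntegerVector k, IntegerMatrix regs,
                                    IntegerMatrix tt, NumericMatrix init,
                                    int runs, int steps, int tail,
                                    IntegerVector clamp, bool async) {
  const int m = k.size();
  const int d = init.ncol();
  if (tail > steps) stop("tail > steps");
  NumericMatrix out(m, d);
  std::vector<int> s(m), ns(m), order(m);
  std::vector<double> acc(m);

  for (int col = 0; col < d; ++col) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int r = 0; r < runs; ++r) {
      for (int j = 0; j < m; ++j) {
        if (clamp[j] >= 0) s[j] = clamp[j];
        else s[j] = (unif_rand() < init(j, col)) ? 1 : 0;
      }
      for (int t = 1; t <= steps; ++t) {
        if (!async) {
          for (int j = 0; j < m; ++j) {
            if (clamp[j] >= 0) { ns[j] = clamp[j]; continue; }
            if (k[j] == 0) { ns[j] = s[j]; continue; }
            int idx = s[regs(j, 0) - 1];
            if (k[j] > 1) idx += 2 * s[regs(j, 1) - 1];
            if (k[j] > 2) idx += 4 * s[regs(j, 2) - 1];
            ns[j] = tt(j, idx);
          }
          std::swap(s, ns);
        } else {
          // one full sweep in a fresh random order, updating in place
          for (int j = 0; j < m; ++j) order[j] = j;
          for (int j = m - 1; j > 0; --j) {
            int u = (int)(unif_rand() * (j + 1));
            if (u > j) u = j;
            std::swap(order[j], order[u]);
          }
          for (int jj = 0; jj < m; ++jj) {
            int j = order[jj];
            if (clamp[j] >= 0) { s[j] = clamp[j]; continue; }
            if (k[j] == 0) continue;
            int idx = s[regs(j, 0) - 1];
            if (k[j] > 1) idx += 2 * s[regs(j, 1) - 1];
            if (k[j] > 2) idx += 4 * s[regs(j, 2) - 1];
            s[j] = tt(j, idx);
          }
        }
        if (t > steps - tail)
          for (int j = 0; j < m; ++j) acc[j] += s[j];
      }
    }
    const double denom = (double)runs * (double)tail;
    for (int j = 0; j < m; ++j) out(j, col) = acc[j] / denom;
  }
  return out;
}

// Regulator-pattern frequencies feeding a node's tail window.
//
// Under synchronous update the state of `node` at time t is a pure function
// of its regulators' bits at t-1, so its tail-averaged activity under ANY
// candidate truth table equals sum_p freq(p) * table[p], where freq is the
// empirical frequency of the regulator bit pattern p over the steps feeding
// the tail. Valid only when the node cannot influence its own regulators
// (checked by the caller); lets a local search score every candidate rule
// from one simulation with shared trajectories.
// [[Rcpp::export]]
NumericMatrix tail_pattern_freq_cpp(IntegerVector k, IntegerMatrix regs,
                                    IntegerMatrix tt, NumericMatrix init,
                                    int runs, int steps, int tail,
                                    IntegerVector clamp, int node) {
  const int m = k.size();
  const int d = init.ncol();
  const int j0 = node - 1;
  if (tail > steps) stop("tail > steps");
  if (k[j0] < 1) stop("node has no regulators");
  NumericMatrix freq(8, d);
  std::vector<int> s(m), ns(m);

  for (int col = 0; col < d; ++col) {
    for (int r = 0; r < runs; ++r) {
      for (int j = 0; j < m; ++j) {
        if (clamp[j] >= 0) s[j] = clamp[j];
        else s[j] = (unif_rand() < init(j, col)) ? 1 : 0;
      }
      for (int t = 1; t <= steps; ++t) {
        if (t > steps - tail) {
          // state at time t-1 is what the node reads for its value at t
          int idx = s[regs(j0, 0) - 1];
          if (k[j0] > 1) idx += 2 * s[regs(j0, 1) - 1];
          if (k[j0] > 2) idx += 4 * s[regs(j0, 2) - 1];
          freq(idx, col) += 1.0;
        }
        for (int j = 0; j < m; ++j) {
          if (clamp[j] >= 0) { ns[j] = clamp[j]; continue; }
          if (k[j] == 0) { ns[j] = s[j]; continue; }
          int idx = s[regs(j, 0) - 1];
          if (k[j] > 1) idx += 2 * s[regs(j, 1) - 1];
          if (k[j] > 2) idx += 4 * s[regs(j, 2) - 1];
          ns[j] = tt(j, idx);
        }
        std::swap(s, ns);
      }
    }
    const double denom = (double)runs * (double)tail;
    for (int p = 0; p < 8; ++p) freq(p, col) /= denom;
  }
  return freq;
}
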