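#include <Rcpp.h>
using namespace Rcpp;

// Synchronous Boolean update to steady state.
//
// reg_idx: per node, 0-based indices of its regulators (empty = input node,
//          holds its state). truth: per node, truth table over the raw states
//          of its regulators, indexed by sum_r state[reg_r] << r.
// clamp_idx >= 0 pins that node to clamp_val at every step (knockout /
// knock-in). Returns the per-node mean over the final `window` states; on a
// fixed point the remaining window is filled analytically.
// [[Rcpp::export]]
NumericVector steady_sim_cpp(List reg_idx, List truth, IntegerVector init,
                             int steps, int window, int clamp_idx,
                             int clamp_val) {
  const int n = init.size();
  if (window < 1 || window > steps + 1)
    stop("window must be in [1, steps + 1]");
  std::vector<int> cur(init.begin(), init.end());
  if (clamp_idx >= 0) cur[clamp_idx] = clamp_val;

  std::vector<std::vector<int>> regs(n);
  std::vector<std::vector<int>> tabs(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector r = reg_idx[i];
    regs[i].assign(r.begin(), r.end());
    IntegerVector t = truth[i];
    tabs[i].assign(t.begin(), t.end());
  }

  std::vector<int> nxt(n);
  std::vector<double> acc(n, 0.0);
  int counted = 0;
  if (window == steps + 1) {  // window covers the initial state too
    for (int i = 0; i < n; ++i) acc[i] += cur[i];
    counted = 1;
  }
  for (int t = 1; t <= steps; ++t) {
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      if (regs[i].empty()) {
        nxt[i] = cur[i];
      } else {
        int idx = 0;
        for (size_t r = 0; r < regs[i].size(); ++r)
          idx |= cur[regs[i][r]] << r;
        nxt[i] = tabs[i][idx];
      }
    }
    if (clamp_idx >= 0) nxt[clamp_idx] = clamp_val;
    for (int i = 0; i < n; ++i)
      if (nxt[i] != cur[i]) { changed = true; break; }
    if (!changed) {
      // fixed point reached at time t-1: every later state equals cur, so the
      // window states not yet accumulated are all cur.
      int remaining = window - counted;
      for (int i = 0; i < n; ++i) acc[i] += (double)cur[i] * remaining;
      counted = window;
      break;
    }
    cur = nxt;
    if (t > steps - window) {
      for (int i = 0; i < n; ++i) acc[i] += cur[i];
      ++counted;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = acc[i] / counted;
  return out;
}
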