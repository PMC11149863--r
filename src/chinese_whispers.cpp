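#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential Chinese Whispers label propagation. Nodes are visited in the
// supplied per-iteration random orders; each node adopts the label with the
// maximum summed edge weight among its neighbors (ties broken toward the
// lowest label id). Isolated nodes keep their initial singleton labels.
// Labels and node ids are 1-based; `orders` has one row per iteration.
// [[Rcpp::export]]
IntegerVector cw_propagate(int n, IntegerVector ei, IntegerVector ej,
                           NumericVector w, IntegerMatrix orders,
                           IntegerVector init) {
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  int m = ei.size();
  for (int k = 0; k < m; ++k) {
    int a = ei[k] - 1, b = ej[k] - 1;
    adj[a].push_back(std::make_pair(b, w[k]));
    adj[b].push_back(std::make_pair(a, w[k]));
  }
  std::vector<int> lab(n);
  for (int v = 0; v < n; ++v) lab[v] = init[v];
  std::vector<double> score(n + 1, 0.0);
  std::vector<int> stamp(n + 1, -1);
  std::vector<int> touched;
  touched.reserve(16);
  for (int it = 0; it < orders.nrow(); ++it) {
    bool changed = false;
    for (int idx = 0; idx < n; ++idx) {
      int v = orders(it, idx) - 1;
      if (adj[v].empty()) continue;
      touched.clear();
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int l = lab[adj[v][k].first];
        if (stamp[l] != it * n + idx) {
          stamp[l] = it * n + idx;
          score[l] = 0.0;
          touched.push_back(l);
        }
        score[l] += adj[v][k].second;
      }
      int best = -1;
      double bs = -1.0;
      for (size_t k = 0; k < touched.size(); ++k) {
        int l = touched[k];
        if (score[l] > bs + 1e-12 ||
            (std::fabs(score[l] - bs) <= 1e-12 && (best < 0 || l < best))) {
          bs = score[l];
          best = l;
        }
      }
      if (best >= 0 && best != lab[v]) {
        lab[v] = best;
        changed = true;
      }
    }
    if (!changed) break;
  }
  return IntegerVector(lab.begin(), lab.end());
}
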