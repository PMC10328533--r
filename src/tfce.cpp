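#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// One-sided threshold-free cluster enhancement on a graph: for each
// threshold h = dh, 2dh, ... up to max(values), nodes with value >= h
// are grouped into connected components (union-find over the edge
// list) and every member accumulates extent^E * h^H * dh.
// Edges are 0-based node index pairs.
// [[Rcpp::export]]
NumericVector tfce_pos_cpp(const NumericVector& values,
                           const IntegerVector& edge_from,
                           const IntegerVector& edge_to,
                           double E, double H, double dh) {
  const int n = values.size(), m = edge_from.size();
  NumericVector out(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) vmax = std::max(vmax, values[i]);
  if (vmax <= 0.0 || dh <= 0.0) return out;
  std::vector<int> parent(n), size(n);
  const int n_thresh = (int)std::floor(vmax / dh + 1e-9);
  for (int s = 1; s <= n_thresh; ++s) {
    const double h = s * dh;
    for (int i = 0; i < n; ++i) { parent[i] = i; size[i] = 1; }
    for (int e = 0; e < m; ++e) {
      const int a = edge_from[e], b = edge_to[e];
      if (values[a] >= h && values[b] >= h) {
        int ra = uf_find(parent, a), rb = uf_find(parent, b);
        if (ra != rb) {
          if (size[ra] < size[rb]) std::swap(ra, rb);
          parent[rb] = ra;
          size[ra] += size[rb];
        }
      }
    }
    const double hH = std::pow(h, H);
    for (int i = 0; i < n; ++i) {
      if (values[i] >= h) {
        const int r = uf_find(parent, i);
        out[i] += std::pow((double)size[r], E) * hH * dh;
      }
    }
  }
  return out;
}
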