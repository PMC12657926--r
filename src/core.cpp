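#include <Rcpp.h>
using namespace Rcpp;

// Per-edge vertex partition counts from a precomputed hop-distance matrix.
// For edge (r, s): alpha_r = #{t : d(r,t) < d(s,t)}, alpha_s symmetric,
// ties = vertices equidistant from both endpoints (including none of the
// endpoints themselves, which always count toward their own side).
// D is v x v integer hop distances; edges is E x 2, 1-based vertex ids.
// [[Rcpp::export]]
IntegerMatrix partition_counts_cpp(const IntegerMatrix& D, const IntegerMatrix& edges) {
  const int v = D.nrow();
  const int ne = edges.nrow();
  IntegerMatrix out(ne, 3);
  const int* dp = INTEGER(D);
  for (int e = 0; e < ne; ++e) {
    const int r = edges(e, 0) - 1;
    const int s = edges(e, 1) - 1;
    // D is symmetric; walk its columns for contiguous access
    const int* dr_col = dp + static_cast<size_t>(r) * v;
    const int* ds_col = dp + static_cast<size_t>(s) * v;
    int ar = 0, as = 0;
    for (int t = 0; t < v; ++t) {
      const int dr = dr_col[t], ds = ds_col[t];
      if (dr < ds) ++ar; else if (ds < dr) ++as;
    }
    out(e, 0) = ar;
    out(e, 1) = as;
    out(e, 2) = v - ar - as;
  }
  return out;
}

// Sequential Watts-Strogatz rewiring of a ring lattice, following the
// original scan order: spans u = 1..delta/2, vertices i = 0..v-1 within each
// span. Each lattice edge (i, i+u mod v) is rewired with probability p to
// (i, j) with j drawn uniformly from the vertices that are neither i nor a
// current neighbour of i. If no eligible target exists the edge is kept.
// Uses R's RNG so set.seed() governs reproducibility.
// Returns an E x 2 edge list (1-based).
// [[Rcpp::export]]
IntegerMatrix ws_rewire_cpp(const int v, const int delta, const double p) {
  const int half = delta / 2;
  const int ne = v * half;
  LogicalMatrix adj(v, v);
  // edge store parallel to the scan; rewired entries are overwritten in place
  IntegerMatrix edges(ne, 2);
  int idx = 0;
  for (int u = 1; u <= half; ++u) {
    for (int i = 0; i < v; ++i) {
      int j = (i + u) % v;
      adj(i, j) = adj(j, i) = true;
      edges(idx, 0) = i; edges(idx, 1) = j; ++idx;
    }
  }
  if (p > 0.0) {
    idx = 0;
    for (int u = 1; u <= half; ++u) {
      for (int i = 0; i < v; ++i, ++idx) {
        if (unif_rand() >= p) continue;
        const int j_old = edges(idx, 1);
        // eligible targets: not i, not currently adjacent to i
        int deg_i = 0;
        for (int t = 0; t < v; ++t) if (adj(i, t)) ++deg_i;
        if (deg_i >= v - 1) continue;  // saturated vertex: keep edge
        int j_new;
        do {
          j_new = static_cast<int>(unif_rand() * v);
          if (j_new >= v) j_new = v - 1;
        } while (j_new == i || adj(i, j_new));
        adj(i, j_old) = adj(j_old, i) = false;
        adj(i, j_new) = adj(j_new, i) = true;
        edges(idx, 1) = j_new;
      }
    }
  }
  IntegerMatrix out(ne, 2);
  for (int e = 0; e < ne; ++e) {
    out(e, 0) = edges(e, 0) + 1;
    out(e, 1) = edges(e, 1) + 1;
  }
  return out;
}
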