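#include <Rcpp.h>
using namespace Rcpp;

// Bespoke disjoint-set forest: path compression + union by size.
// Kept deliberately free of any graph-library dependency so that the
// connected-components oracle used in the tests is genuinely independent.
struct DisjointSet {
  std::vector<int> parent;
  std::vector<int> size;      // node count per root
  std::vector<int> m;         // internal edge count per root
  std::vector<double> ssum;   // internal strength sum per root

  explicit DisjointSet(int n) : parent(n), size(n, 1), m(n, 0), ssum(n, 0.0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }

  int find(int x) {
    int root = x;
    while (parent[root] != root) root = parent[root];
    while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
    return root;
  }

  // returns the surviving root
  int unite(int ra, int rb) {
    if (size[ra] < size[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    size[ra] += size[rb];
    m[ra] += m[rb];
    ssum[ra] += ssum[rb];
    return ra;
  }
};

static inline double comp_density(int s, int m) {
  return (double)m / ((double)s * (s - 1) / 2.0);
}

// Percolation sweep over edges pre-sorted by decreasing ordering key.
// a, b: 1-based node indices; step: 1-based tie-group index, non-decreasing;
// strength: raw strengths (only used for bookkeeping totals).
// Returns the per-edge merge kind (1 new_pair, 2 absorb, 3 merge, 4 intra)
// and one row of aggregate component statistics per step, recorded after all
// edges of the tie group are admitted.
// [[Rcpp::export]]
List percolate_sweep(IntegerVector a, IntegerVector b, IntegerVector step,
                     NumericVector strength, int n_nodes) {
  const int ne = a.size();
  const int ns = ne > 0 ? step[ne - 1] : 0;
  DisjointSet ds(n_nodes);

  IntegerVector kind(ne);
  IntegerVector edges_added(ns), cum_edges(ns), n_subgraphs(ns), n_triples(ns),
      n_clustered(ns), max_size(ns);
  NumericVector sum_density(ns);

  // running aggregates over components of size >= 2
  int subs = 0, triples = 0, clustered = 0, maxsz = 0;
  double dens_sum = 0.0;
  int in_step_added = 0, cum = 0;

  // nodes start "unclustered": a size-1 tree is not a component
  for (int i = 0; i < ne; ++i) {
    const int u = a[i] - 1, v = b[i] - 1;
    const int ru = ds.find(u), rv = ds.find(v);
    const bool u_cl = ds.size[ru] >= 2, v_cl = ds.size[rv] >= 2;

    if (ru == rv) {
      // intra-cluster edge: no structural change, density/strength updated
      dens_sum -= comp_density(ds.size[ru], ds.m[ru]);
      ds.m[ru] += 1;
      ds.ssum[ru] += strength[i];
      dens_sum += comp_density(ds.size[ru], ds.m[ru]);
      kind[i] = 4;
    } else if (!u_cl && !v_cl) {
      int r = ds.unite(ru, rv);
      ds.m[r] = 1;
      ds.ssum[r] = strength[i];
      subs += 1;
      clustered += 2;
      dens_sum += 1.0;  // two nodes, one edge
      if (ds.size[r] > maxsz) maxsz = ds.size[r];
      kind[i] = 1;
    } else if (u_cl != v_cl) {
      // absorb the unclustered endpoint into the existing cluster
      const int rc = u_cl ? ru : rv;
      dens_sum -= comp_density(ds.size[rc], ds.m[rc]);
      const int old_sz = ds.size[rc];
      int r = ds.unite(ru, rv);
      ds.m[r] += 1;
      ds.ssum[r] += strength[i];
      dens_sum += comp_density(ds.size[r], ds.m[r]);
      clustered += 1;
      if (old_sz < 3 && ds.size[r] >= 3) triples += 1;
      if (ds.size[r] > maxsz) maxsz = ds.size[r];
      kind[i] = 2;
    } else {
      // two existing clusters merge
      dens_sum -= comp_density(ds.size[ru], ds.m[ru]);
      dens_sum -= comp_density(ds.size[rv], ds.m[rv]);
      triples -= (ds.size[ru] >= 3) + (ds.size[rv] >= 3);
      int r = ds.unite(ru, rv);
      ds.m[r] += 1;
      ds.ssum[r] += strength[i];
      dens_sum += comp_density(ds.size[r], ds.m[r]);
      subs -= 1;
      triples += 1;  // merged component has >= 4 members
      if (ds.size[r] > maxsz) maxsz = ds.size[r];
      kind[i] = 3;
    }

    in_step_added += 1;
    cum += 1;
    const bool last_of_step = (i == ne - 1) || (step[i + 1] != step[i]);
    if (last_of_step) {
      const int s = step[i] - 1;
      edges_added[s] = in_step_added;
      cum_edges[s] = cum;
      n_subgraphs[s] = subs;
      n_triples[s] = triples;
      n_clustered[s] = clustered;
      max_size[s] = maxsz;
      sum_density[s] = dens_sum;
      in_step_added = 0;
    }
  }

  return List::create(
      _["kind"] = kind, _["edges_added"] = edges_added,
      _["cumulative_edges"] = cum_edges, _["n_subgraphs"] = n_subgraphs,
      _["n_triples"] = n_triples, _["n_clustered"] = n_clustered,
      _["max_size"] = max_size, _["sum_density"] = sum_density);
}

// Component label (arbitrary but stable root index, 1-based) for every node
// after admitting the first k edges; NA for nodes touched by no admitted edge.
// [[Rcpp::export]]
IntegerVector components_upto(IntegerVector a, IntegerVector b, int k,
                              int n_nodes) {
  DisjointSet ds(n_nodes);
  std::vector<bool> touched(n_nodes, false);
  for (int i = 0; i < k; ++i) {
    const int u = a[i] - 1, v = b[i] - 1;
    touched[u] = true;
    touched[v] = true;
    const int ru = ds.find(u), rv = ds.find(v);
    if (ru != rv) ds.unite(ru, rv);
  }
  IntegerVector lab(n_nodes);
  for (int i = 0; i < n_nodes; ++i)
    lab[i] = touched[i] ? ds.find(i) + 1 : NA_INTEGER;
  return lab;
}
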