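// Vietoris-Rips persistent homology over Z/2 up to dimension 2.
//
// Standard boundary-matrix column reduction, one dimension at a time:
// dimension-0 pairs come from a union-find sweep over the sorted edges;
// H1 pairs from reducing the triangle boundary matrix against edges; H2
// pairs from reducing the tetrahedron boundary matrix against triangles.
// The maximal edge of any cycle is a positive (cycle-creating) simplex, so
// per-dimension reduction yields the global pairing. Capping the filtration
// at the enclosing radius (min over points of its max distance) is exact:
// the complex becomes a cone there, hence acyclic above dimension 0.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

struct Simplex {
  double diam;
  int v0, v1, v2, v3;  // unused slots = -1
};

static bool simplex_less(const Simplex& a, const Simplex& b) {
  if (a.diam != b.diam) return a.diam < b.diam;
  if (a.v0 != b.v0) return a.v0 < b.v0;
  if (a.v1 != b.v1) return a.v1 < b.v1;
  if (a.v2 != b.v2) return a.v2 < b.v2;
  return a.v3 < b.v3;
}

// symmetric difference of two sorted index vectors (Z/2 column addition)
static void add_columns(std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  a.swap(out);
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

// Reduce columns (boundaries, as sorted row-position vectors) against rows.
// Records pairs (row, column) and flags which columns reduced to zero
// (positive) and which rows became pivots.
static void reduce_matrix(const std::vector<std::vector<int>>& boundaries,
                          const std::vector<double>& col_diam,
                          const std::vector<double>& row_diam,
                          std::vector<char>& row_is_pivot,
                          std::vector<char>& col_is_positive,
                          std::vector<double>& births,
                          std::vector<double>& deaths) {
  const size_t n_rows = row_diam.size();
  std::vector<std::vector<int>> pivot_data(n_rows);
  std::vector<char> has_pivot(n_rows, 0);
  for (size_t c = 0; c < boundaries.size(); ++c) {
    std::vector<int> cur = boundaries[c];
    bool found_pivot = false;
    while (!cur.empty()) {
      int low = cur.back();
      if (!has_pivot[low]) {
        has_pivot[low] = 1;
        row_is_pivot[low] = 1;
        if (col_diam[c] > row_diam[low]) {
          births.push_back(row_diam[low]);
          deaths.push_back(col_diam[c]);
        }
        pivot_data[low].swap(cur);
        found_pivot = true;
        break;
      }
      add_columns(cur, pivot_data[low]);
    }
    if (!found_pivot) col_is_positive[c] = 1;
  }
}

static List rips_cohomology(NumericMatrix dist, int maxdim, double threshold);

// Cohomology-style reduction (anti-transpose): columns are p-simplices in
// decreasing filtration order holding their cofacet rows ((p+1)-simplices,
// also in decreasing order); pivot pairs are exactly the dimension-p
// persistence pairs. Columns known to be negative in dimension p-1 are
// cleared (skipped); remaining zero columns are essential classes. This is
// the fast path: the number of columns equals the number of p-simplices.
//
// cofacet_rows(c) must return the column's cofacet row ids sorted
// ascending (descending filtration positions map to ascending ids).
static void reduce_cohomology(
    const std::vector<std::vector<int>>& columns,   // cofacet row ids, sorted
    const std::vector<double>& col_diam,
    const std::vector<char>& col_cleared,
    const std::vector<double>& row_diam,            // indexed by row id
    std::vector<char>& row_is_pivot,
    std::vector<char>& col_essential,
    std::vector<double>& births,
    std::vector<double>& deaths) {
  std::unordered_map<int, std::vector<int>> pivot_data;
  pivot_data.reserve(columns.size() * 2);
  for (size_t c = 0; c < columns.size(); ++c) {
    if (col_cleared[c]) continue;
    std::vector<int> cur = columns[c];
    bool found = false;
    while (!cur.empty()) {
      int low = cur.back();
      auto it = pivot_data.find(low);
      if (it == pivot_data.end()) {
        row_is_pivot[low] = 1;
        if (row_diam[low] > col_diam[c]) {
          births.push_back(col_diam[c]);
          deaths.push_back(row_diam[low]);
        }
        pivot_data.emplace(low, std::move(cur));
        found = true;
        break;
      }
      add_columns(cur, it->second);
    }
    if (!found) col_essential[c] = 1;
  }
}

// [[Rcpp::export]]
List cpp_rips_persistence(NumericMatrix dist, int maxdim, double threshold,
                          std::string method = "cohomology") {
  if (method == "cohomology")
    return rips_cohomology(dist, maxdim, threshold);
  const int n = dist.nrow();
  if (maxdim < 0 || maxdim > 2) stop("maxdim must be 0, 1 or 2");

  // enumerate edges under the threshold, sorted by (diameter, vertices)
  std::vector<Simplex> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = dist(i, j);
      if (d <= threshold) edges.push_back({d, i, j, -1, -1});
    }
  std::sort(edges.begin(), edges.end(), simplex_less);

  // ---- dimension 0: union-find over sorted edges ----
  std::vector<double> b0, d0;
  UnionFind uf(n);
  std::vector<char> edge_negative(edges.size(), 0);
  int components = n;
  for (size_t e = 0; e < edges.size(); ++e) {
    int ra = uf.find(edges[e].v0), rb = uf.find(edges[e].v1);
    if (ra != rb) {
      uf.parent[ra] = rb;
      edge_negative[e] = 1;
      --components;
      if (edges[e].diam > 0.0) { b0.push_back(0.0); d0.push_back(edges[e].diam); }
    }
  }
  for (int c = 0; c < components; ++c) { b0.push_back(0.0); d0.push_back(R_PosInf); }

  List out(maxdim + 1);
  {
    NumericMatrix m0(b0.size(), 2);
    for (size_t i = 0; i < b0.size(); ++i) { m0(i, 0) = b0[i]; m0(i, 1) = d0[i]; }
    out[0] = m0;
  }
  if (maxdim == 0) return out;

  // edge row positions keyed by (i, j)
  std::unordered_map<long long, int> edge_pos;
  edge_pos.reserve(edges.size() * 2);
  std::vector<double> edge_diam(edges.size());
  for (size_t e = 0; e < edges.size(); ++e) {
    edge_pos[(long long)edges[e].v0 * n + edges[e].v1] = (int)e;
    edge_diam[e] = edges[e].diam;
  }

  // ---- triangles ----
  std::vector<Simplex> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dist(i, j);
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double d = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (d <= threshold) tris.push_back({d, i, j, k, -1});
      }
    }
  std::sort(tris.begin(), tris.end(), simplex_less);

  std::vector<std::vector<int>> tri_bound(tris.size());
  std::vector<double> tri_diam(tris.size());
  for (size_t t = 0; t < tris.size(); ++t) {
    const Simplex& s = tris[t];
    tri_diam[t] = s.diam;
    std::vector<int> rows = {
      edge_pos[(long long)s.v0 * n + s.v1],
      edge_pos[(long long)s.v0 * n + s.v2],
      edge_pos[(long long)s.v1 * n + s.v2]};
    std::sort(rows.begin(), rows.end());
    tri_bound[t] = rows;
  }

  std::vector<char> edge_is_pivot(edges.size(), 0);
  std::vector<char> tri_positive(tris.size(), 0);
  std::vector<double> b1, d1;
  reduce_matrix(tri_bound, tri_diam, edge_diam, edge_is_pivot, tri_positive, b1, d1);
  // positive (cycle-creating) edges never destroyed: essential H1 classes
  for (size_t e = 0; e < edges.size(); ++e)
    if (!edge_negative[e] && !edge_is_pivot[e]) {
      b1.push_back(edge_diam[e]);
      d1.push_back(R_PosInf);
    }
  {
    NumericMatrix m1(b1.size(), 2);
    for (size_t i = 0; i < b1.size(); ++i) { m1(i, 0) = b1[i]; m1(i, 1) = d1[i]; }
    out[1] = m1;
  }
  if (maxdim == 1) return out;

  // triangle row positions keyed by (i, j, k)
  std::unordered_map<long long, int> tri_pos;
  tri_pos.reserve(tris.size() * 2);
  for (size_t t = 0; t < tris.size(); ++t) {
    const Simplex& s = tris[t];
    tri_pos[((long long)s.v0 * n + s.v1) * n + s.v2] = (int)t;
  }

  // ---- tetrahedra ----
  std::vector<Simplex> tets;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dist(i, j);
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double dijk = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (dijk > threshold) continue;
        for (int l = k + 1; l < n; ++l) {
          double d = std::max(dijk, std::max(dist(i, l),
                       std::max(dist(j, l), dist(k, l))));
          if (d <= threshold) tets.push_back({d, i, j, k, l});
        }
      }
    }
  std::sort(tets.begin(), tets.end(), simplex_less);

  std::vector<std::vector<int>> tet_bound(tets.size());
  std::vector<double> tet_diam(tets.size());
  for (size_t t = 0; t < tets.size(); ++t) {
    const Simplex& s = tets[t];
    tet_diam[t] = s.diam;
    std::vector<int> rows = {
      tri_pos[((long long)s.v0 * n + s.v1) * n + s.v2],
      tri_pos[((long long)s.v0 * n + s.v1) * n + s.v3],
      tri_pos[((long long)s.v0 * n + s.v2) * n + s.v3],
      tri_pos[((long long)s.v1 * n + s.v2) * n + s.v3]};
    std::sort(rows.begin(), rows.end());
    tet_bound[t] = rows;
  }

  std::vector<char> tri_is_pivot(tris.size(), 0);
  std::vector<char> tet_positive(tets.size(), 0);
  std::vector<double> b2, d2;
  reduce_matrix(tet_bound, tet_diam, tri_diam, tri_is_pivot, tet_positive, b2, d2);
  for (size_t t = 0; t < tris.size(); ++t)
    if (tri_positive[t] && !tri_is_pivot[t]) {
      b2.push_back(tri_diam[t]);
      d2.push_back(R_PosInf);
    }
  {
    NumericMatrix m2(b2.size(), 2);
    for (size_t i = 0; i < b2.size(); ++i) { m2(i, 0) = b2[i]; m2(i, 1) = d2[i]; }
    out[2] = m2;
  }
  return out;
}

static List rips_cohomology(NumericMatrix dist, int maxdim, double threshold) {
  const int n = dist.nrow();
  if (maxdim < 0 || maxdim > 2) stop("maxdim must be 0, 1 or 2");

  std::vector<Simplex> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = dist(i, j);
      if (d <= threshold) edges.push_back({d, i, j, -1, -1});
    }
  std::sort(edges.begin(), edges.end(), simplex_less);
  const int n_edges = (int)edges.size();

  // dimension 0 via union-find
  std::vector<double> b0, d0;
  UnionFind uf(n);
  std::vector<char> edge_negative(n_edges, 0);
  int components = n;
  for (int e = 0; e < n_edges; ++e) {
    int ra = uf.find(edges[e].v0), rb = uf.find(edges[e].v1);
    if (ra != rb) {
      uf.parent[ra] = rb;
      edge_negative[e] = 1;
      --components;
      if (edges[e].diam > 0.0) { b0.push_back(0.0); d0.push_back(edges[e].diam); }
    }
  }
  for (int c = 0; c < components; ++c) { b0.push_back(0.0); d0.push_back(R_PosInf); }

  List out(maxdim + 1);
  {
    NumericMatrix m0(b0.size(), 2);
    for (size_t i = 0; i < b0.size(); ++i) { m0(i, 0) = b0[i]; m0(i, 1) = d0[i]; }
    out[0] = m0;
  }
  if (maxdim == 0) return out;

  // triangles, ascending filtration order, with position lookup
  std::vector<Simplex> tris;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dist(i, j);
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double d = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (d <= threshold) tris.push_back({d, i, j, k, -1});
      }
    }
  std::sort(tris.begin(), tris.end(), simplex_less);
  const int n_tris = (int)tris.size();
  std::unordered_map<long long, int> tri_asc;
  tri_asc.reserve(tris.size() * 2);
  for (int t = 0; t < n_tris; ++t) {
    const Simplex& s = tris[t];
    tri_asc[((long long)s.v0 * n + s.v1) * n + s.v2] = t;
  }
  std::vector<double> tri_row_diam(n_tris);   // indexed by descending row id
  for (int t = 0; t < n_tris; ++t) tri_row_diam[n_tris - 1 - t] = tris[t].diam;

  // H1: columns = edges in decreasing order, entries = triangle cofacets
  std::vector<std::vector<int>> cols1(n_edges);
  std::vector<double> cdiam1(n_edges);
  std::vector<char> cleared1(n_edges, 0);
  for (int cd = 0; cd < n_edges; ++cd) {
    int e = n_edges - 1 - cd;               // ascending index
    cdiam1[cd] = edges[e].diam;
    if (edge_negative[e]) { cleared1[cd] = 1; continue; }
    int a = edges[e].v0, b = edges[e].v1;
    std::vector<int>& col = cols1[cd];
    for (int k = 0; k < n; ++k) {
      if (k == a || k == b) continue;
      double d = std::max(edges[e].diam, std::max(dist(a, k), dist(b, k)));
      if (d > threshold) continue;
      int x = std::min(a, std::min(b, k));
      int z = std::max(a, std::max(b, k));
      int y = a + b + k - x - z;
      int t = tri_asc[((long long)x * n + y) * n + z];
      col.push_back(n_tris - 1 - t);
    }
    std::sort(col.begin(), col.end());
  }
  std::vector<char> tri_row_pivot(n_tris, 0);
  std::vector<char> edge_essential(n_edges, 0);
  std::vector<double> b1, d1;
  reduce_cohomology(cols1, cdiam1, cleared1, tri_row_diam,
                    tri_row_pivot, edge_essential, b1, d1);
  for (int cd = 0; cd < n_edges; ++cd)
    if (edge_essential[cd]) { b1.push_back(cdiam1[cd]); d1.push_back(R_PosInf); }
  {
    NumericMatrix m1(b1.size(), 2);
    for (size_t i = 0; i < b1.size(); ++i) { m1(i, 0) = b1[i]; m1(i, 1) = d1[i]; }
    out[1] = m1;
  }
  if (maxdim == 1) return out;

  // tetrahedra, ascending order, with position lookup
  std::vector<Simplex> tets;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dij = dist(i, j);
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double dijk = std::max(dij, std::max(dist(i, k), dist(j, k)));
        if (dijk > threshold) continue;
        for (int l = k + 1; l < n; ++l) {
          double d = std::max(dijk, std::max(dist(i, l),
                       std::max(dist(j, l), dist(k, l))));
          if (d <= threshold) tets.push_back({d, i, j, k, l});
        }
      }
    }
  std::sort(tets.begin(), tets.end(), simplex_less);
  const int n_tets = (int)tets.size();
  std::unordered_map<long long, int> tet_asc;
  tet_asc.reserve(tets.size() * 2);
  for (int t = 0; t < n_tets; ++t) {
    const Simplex& s = tets[t];
    tet_asc[(((long long)s.v0 * n + s.v1) * n + s.v2) * n + s.v3] = t;
  }
  std::vector<double> tet_row_diam(n_tets);
  for (int t = 0; t < n_tets; ++t) tet_row_diam[n_tets - 1 - t] = tets[t].diam;

  // H2: columns = triangles in decreasing order; clear pivot rows from H1
  std::vector<std::vector<int>> cols2(n_tris);
  std::vector<double> cdiam2(n_tris);
  std::vector<char> cleared2(n_tris, 0);
  for (int cd = 0; cd < n_tris; ++cd) {
    int t = n_tris - 1 - cd;
    cdiam2[cd] = tris[t].diam;
    if (tri_row_pivot[cd]) { cleared2[cd] = 1; continue; }  // row id == cd
    int a = tris[t].v0, b = tris[t].v1, c = tris[t].v2;
    std::vector<int>& col = cols2[cd];
    for (int k = 0; k < n; ++k) {
      if (k == a || k == b || k == c) continue;
      double d = std::max(tris[t].diam, std::max(dist(a, k),
                   std::max(dist(b, k), dist(c, k))));
      if (d > threshold) continue;
      int v[4] = {a, b, c, k};
      std::sort(v, v + 4);
      int tt = tet_asc[(((long long)v[0] * n + v[1]) * n + v[2]) * n + v[3]];
      col.push_back(n_tets - 1 - tt);
    }
    std::sort(col.begin(), col.end());
  }
  std::vector<char> tet_row_pivot(n_tets, 0);
  std::vector<char> tri_essential(n_tris, 0);
  std::vector<double> b2, d2;
  reduce_cohomology(cols2, cdiam2, cleared2, tet_row_diam,
                    tet_row_pivot, tri_essential, b2, d2);
  for (int cd = 0; cd < n_tris; ++cd)
    if (tri_essential[cd]) { b2.push_back(cdiam2[cd]); d2.push_back(R_PosInf); }
  {
    NumericMatrix m2(b2.size(), 2);
    for (size_t i = 0; i < b2.size(); ++i) { m2(i, 0) = b2[i]; m2(i, 1) = d2[i]; }
    out[2] = m2;
  }
  return out;
}
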