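#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

// Vietoris-Rips persistence over Z/2 by boundary-matrix reduction.
// Simplices up to dimension max_dim + 1 are enumerated (cofaces one
// dimension above max_dim are needed to pair deaths of max_dim classes);
// classes of dimension <= max_dim are reported. The filtration value of a
// simplex is the largest pairwise distance among its vertices; simplices
// above max_edge are not entered, so classes alive at max_edge are
// returned as essential (capped).

namespace {

struct Simplex {
  double value;
  int dim;
  std::uint64_t key;   // packed sorted vertices, 8 bits each
  int v[4];            // vertices (dim + 1 used)
};

inline std::uint64_t pack(const int *v, int m) {
  std::uint64_t k = 0;
  for (int i = 0; i < m; ++i) k = (k << 8) | (std::uint64_t)(v[i] + 1);
  return k;
}

// symmetric difference of two sorted index vectors (Z/2 column addition)
void add_column(std::vector<int> &a, const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  a.swap(out);
}

} // namespace

// [[Rcpp::export]]
Rcpp::NumericMatrix vr_persistence_cpp(Rcpp::NumericMatrix dist, int max_dim,
                                       double max_edge) {
  const int n = dist.nrow();
  if (dist.ncol() != n) Rcpp::stop("distance matrix must be square");
  const int top_dim = max_dim + 1;

  std::vector<Simplex> simp;
  simp.reserve((size_t)n * n);

  int v[4];
  for (int i = 0; i < n; ++i) {
    v[0] = i;
    simp.push_back({0.0, 0, pack(v, 1), {i, 0, 0, 0}});
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = dist(i, j);
      if (d <= max_edge) {
        v[0] = i; v[1] = j;
        simp.push_back({d, 1, pack(v, 2), {i, j, 0, 0}});
      }
    }
  if (top_dim >= 2) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dij = dist(i, j);
        if (dij > max_edge) continue;
        for (int k = j + 1; k < n; ++k) {
          double d = std::max(dij, std::max(dist(i, k), dist(j, k)));
          if (d <= max_edge) {
            v[0] = i; v[1] = j; v[2] = k;
            simp.push_back({d, 2, pack(v, 3), {i, j, k, 0}});
          }
        }
      }
  }
  if (top_dim >= 3) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dij = dist(i, j);
        if (dij > max_edge) continue;
        for (int k = j + 1; k < n; ++k) {
          double dijk = std::max(dij, std::max(dist(i, k), dist(j, k)));
          if (dijk > max_edge) continue;
          for (int l = k + 1; l < n; ++l) {
            double d = std::max(dijk, std::max(dist(i, l),
                         std::max(dist(j, l), dist(k, l))));
            if (d <= max_edge) {
              v[0] = i; v[1] = j; v[2] = k; v[3] = l;
              simp.push_back({d, 3, pack(v, 4), {i, j, k, l}});
            }
          }
        }
      }
  }

  const size_t m = simp.size();
  std::vector<size_t> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (simp[a].value != simp[b].value) return simp[a].value < simp[b].value;
    if (simp[a].dim != simp[b].dim) return simp[a].dim < simp[b].dim;
    return simp[a].key < simp[b].key;
  });

  std::unordered_map<std::uint64_t, int> index;
  index.reserve(m * 2);
  std::vector<const Simplex *> s(m);
  for (size_t pos = 0; pos < m; ++pos) {
    s[pos] = &simp[ord[pos]];
    index[s[pos]->key] = (int)pos;
  }

  // boundary columns
  std::vector<std::vector<int>> col(m);
  for (size_t pos = 0; pos < m; ++pos) {
    const Simplex *sx = s[pos];
    if (sx->dim == 0) continue;
    std::vector<int> c;
    c.reserve(sx->dim + 1);
    int face[4];
    for (int drop = 0; drop <= sx->dim; ++drop) {
      int t = 0;
      for (int q = 0; q <= sx->dim; ++q)
        if (q != drop) face[t++] = sx->v[q];
      c.push_back(index[pack(face, sx->dim)]);
    }
    std::sort(c.begin(), c.end());
    col[pos] = std::move(c);
  }

  // reduction
  std::vector<int> low_of(m, -1); // pivot row -> column holding it
  std::vector<char> is_pivot_row(m, 0);
  std::vector<char> is_positive(m, 0); // column reduced to zero (creator)
  for (size_t j = 0; j < m; ++j) {
    std::vector<int> &c = col[j];
    while (!c.empty()) {
      int lo = c.back();
      int other = low_of[lo];
      if (other < 0) break;
      add_column(c, col[other]);
    }
    if (c.empty()) {
      is_positive[j] = 1;
    } else {
      int lo = c.back();
      low_of[lo] = (int)j;
      is_pivot_row[lo] = 1;
    }
  }

  std::vector<double> dims, births, deaths, capped;
  for (size_t j = 0; j < m; ++j) {
    if (!is_positive[j]) continue;      // only creators give classes
    int d = s[j]->dim;
    if (d > max_dim) continue;
    double b = s[j]->value;
    if (is_pivot_row[j]) {              // paired: dies at its killer
      double de = s[low_of[j]]->value;
      if (de > b) {
        dims.push_back(d); births.push_back(b);
        deaths.push_back(de); capped.push_back(0);
      }
    } else {                            // essential: capped at max_edge
      dims.push_back(d); births.push_back(b);
      deaths.push_back(max_edge); capped.push_back(1);
    }
  }

  Rcpp::NumericMatrix out((int)dims.size(), 4);
  for (int i = 0; i < (int)dims.size(); ++i) {
    out(i, 0) = dims[i]; out(i, 1) = births[i];
    out(i, 2) = deaths[i]; out(i, 3) = capped[i];
  }
  Rcpp::colnames(out) =
      Rcpp::CharacterVector::create("dimension", "birth", "death", "capped");
  return out;
}
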