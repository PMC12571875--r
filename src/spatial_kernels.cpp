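#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <functional>
#include <map>
#include <vector>
using namespace Rcpp;

// k nearest neighbours (excluding self) by brute force; n is small per sample.
// Returns 1-based index matrix n x k. Ties broken by index order.
// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  if (k >= n) k = n - 1;
  IntegerMatrix out(n, std::max(k, 0));
  if (k <= 0) return out;
  std::vector<double> d(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      d[j] = dx * dx + dy * dy;
      idx[j] = j;
    }
    d[i] = R_PosInf;
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) { return d[a] < d[b] || (d[a] == d[b] && a < b); });
    for (int m = 0; m < k; ++m) out(i, m) = idx[m] + 1;
  }
  return out;
}

// k nearest neighbours in d dimensions (rows of X), excluding self.
// [[Rcpp::export(name = ".knn_brute_nd")]]
IntegerMatrix knn_brute_nd(NumericMatrix X, int k) {
  int n = X.nrow(), d = X.ncol();
  if (k >= n) k = n - 1;
  IntegerMatrix out(n, std::max(k, 0));
  if (k <= 0) return out;
  // row-major copy so the inner product walks contiguous memory
  std::vector<double> buf((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < d; ++m) buf[(size_t)i * d + m] = X(i, m);
  std::vector<double> dist(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    const double *pi = &buf[(size_t)i * d];
    for (int j = 0; j < n; ++j) {
      const double *pj = &buf[(size_t)j * d];
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        double diff = pi[m] - pj[m];
        s += diff * diff;
      }
      dist[j] = s;
      idx[j] = j;
    }
    dist[i] = R_PosInf;
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) { return dist[a] < dist[b] || (dist[a] == dist[b] && a < b); });
    for (int m = 0; m < k; ++m) out(i, m) = idx[m] + 1;
  }
  return out;
}

// For each query point, distance to the nearest reference point and its index.
// [[Rcpp::export(name = ".nearest_ref_dist")]]
List nearest_ref_dist(NumericVector qx, NumericVector qy,
                      NumericVector rx, NumericVector ry) {
  int nq = qx.size(), nr = rx.size();
  NumericVector dist(nq);
  IntegerVector which(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    int bidx = NA_INTEGER;
    for (int j = 0; j < nr; ++j) {
      double dx = qx[i] - rx[j], dy = qy[i] - ry[j];
      double dd = dx * dx + dy * dy;
      if (dd < best) { best = dd; bidx = j + 1; }
    }
    dist[i] = std::sqrt(best);
    which[i] = bidx;
  }
  return List::create(_["dist"] = dist, _["index"] = which);
}

// Count pairs between two point sets within a Euclidean range.
// [[Rcpp::export(name = ".count_pairs_within")]]
double count_pairs_within(NumericVector ax, NumericVector ay,
                          NumericVector bx, NumericVector by,
                          double range) {
  int na = ax.size(), nb = bx.size();
  double r2 = range * range, cnt = 0.0;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      if (dx * dx + dy * dy <= r2) cnt += 1.0;
    }
  }
  return cnt;
}

// Count, for every ordered pair of type labels (1..K), the number of
// point pairs within range. Diagonal blocks count ordered pairs i != j.
// [[Rcpp::export(name = ".pair_count_matrix")]]
NumericMatrix pair_count_matrix(NumericVector x, NumericVector y,
                                IntegerVector type, int K, double range) {
  NumericMatrix out(K, K);
  int n = x.size();
  double r2 = range * range;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= r2) {
        out(type[i] - 1, type[j] - 1) += 1.0;
        out(type[j] - 1, type[i] - 1) += 1.0;
      }
    }
  }
  return out;
}

// Single-linkage connected components with edges <= link distance.
// Union-find over all point pairs; returns 1-based component id per point.
// [[Rcpp::export(name = ".link_components")]]
IntegerVector link_components(NumericVector x, NumericVector y, double link) {
  int n = x.size();
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  double l2 = link * link;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= l2) {
        int ra = find(i), rb = find(j);
        if (ra != rb) parent[ra] = rb;
      }
    }
  }
  IntegerVector comp(n);
  std::map<int, int> relabel;
  int nxt = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++nxt; comp[i] = nxt; }
    else comp[i] = it->second;
  }
  return comp;
}
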