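#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// componentwise median; even counts average the two middle order statistics,
// matching stats::median
static double median_of(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

static inline double l1_dist(const double* xi, const double* c, int p) {
  double d = 0.0;
  for (int f = 0; f < p; ++f) d += std::fabs(xi[f] - c[f]);
  return d;
}

// One Lloyd run of L1 k-means from given initial centroids.
// Assignment ties go to the lowest centroid index; centroid update is the
// componentwise median; empty clusters are re-seeded from the point
// currently farthest from its assigned centroid.
// [[Rcpp::export]]
List lloyd_l1_cpp(NumericMatrix x, NumericMatrix init, int max_iter) {
  const int n = x.nrow(), p = x.ncol(), k = init.nrow();
  // transposed copy: each point contiguous for cache-friendly distance scans
  std::vector<double> xt((size_t) n * p);
  for (int f = 0; f < p; ++f)
    for (int i = 0; i < n; ++i) xt[(size_t) i * p + f] = x(i, f);
  std::vector<std::vector<double> > cent(k, std::vector<double>(p));
  for (int j = 0; j < k; ++j)
    for (int f = 0; f < p; ++f) cent[j][f] = init(j, f);

  std::vector<int> assign_old(n, -1), assign_new(n, 0);
  std::vector<double> dmin(n, 0.0);
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      const double* xi = &xt[(size_t) i * p];
      int best = 0;
      double bestd = l1_dist(xi, cent[0].data(), p);
      for (int j = 1; j < k; ++j) {
        double d = l1_dist(xi, cent[j].data(), p);
        if (d < bestd) { bestd = d; best = j; }
      }
      assign_new[i] = best;
      dmin[i] = bestd;
    }
    // re-seed empty clusters from the worst-fit point
    for (;;) {
      std::vector<int> sizes(k, 0);
      for (int i = 0; i < n; ++i) sizes[assign_new[i]]++;
      int empty = -1;
      for (int j = 0; j < k; ++j) if (sizes[j] == 0) { empty = j; break; }
      if (empty < 0) break;
      int far = 0;
      for (int i = 1; i < n; ++i) if (dmin[i] > dmin[far]) far = i;
      for (int f = 0; f < p; ++f) cent[empty][f] = xt[(size_t) far * p + f];
      for (int i = 0; i < n; ++i) {
        const double* xi = &xt[(size_t) i * p];
        int best = 0;
        double bestd = l1_dist(xi, cent[0].data(), p);
        for (int j = 1; j < k; ++j) {
          double d = l1_dist(xi, cent[j].data(), p);
          if (d < bestd) { bestd = d; best = j; }
        }
        assign_new[i] = best;
        dmin[i] = bestd;
      }
    }
    if (assign_new == assign_old) break;
    assign_old = assign_new;
    std::vector<double> buf;
    for (int j = 0; j < k; ++j) {
      for (int f = 0; f < p; ++f) {
        buf.clear();
        for (int i = 0; i < n; ++i)
          if (assign_new[i] == j) buf.push_back(xt[(size_t) i * p + f]);
        cent[j][f] = median_of(buf);
      }
    }
  }

  // final assignment against the final centroids
  double dispersion = 0.0;
  IntegerVector cluster(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xt[(size_t) i * p];
    int best = 0;
    double bestd = l1_dist(xi, cent[0].data(), p);
    for (int j = 1; j < k; ++j) {
      double d = l1_dist(xi, cent[j].data(), p);
      if (d < bestd) { bestd = d; best = j; }
    }
    cluster[i] = best + 1;
    dispersion += bestd;
  }
  NumericMatrix centroids(k, p);
  for (int j = 0; j < k; ++j)
    for (int f = 0; f < p; ++f) centroids(j, f) = cent[j][f];

  return List::create(_["centroids"] = centroids, _["cluster"] = cluster,
                      _["dispersion"] = dispersion,
                      _["iterations"] = std::min(it, max_iter));
}
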