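#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sequential Kohonen training.
// X: n x k inputs (normalized), M: N x k initial codebook (modified copy
// returned), lat: N x 2 lattice coordinates, phases: rows of
// (t_max, alpha0, alpha1, sigma0, sigma1).  Uses R's RNG for input
// sampling so results are reproducible under set.seed().
// Updates are truncated at 3 sigma lattice distance, where the Gaussian
// neighborhood is below 1.2e-2 of its peak.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix X, NumericMatrix M,
                            NumericMatrix lat, NumericMatrix phases) {
  const int n = X.nrow(), k = X.ncol(), N = M.nrow();
  // row-major contiguous copies: node/input vectors have stride k
  std::vector<double> xs((size_t) n * k), cb((size_t) N * k);
  std::vector<double> lx(N), ly(N);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) xs[(size_t) i * k + j] = X(i, j);
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < k; ++j) cb[(size_t) i * k + j] = M(i, j);
    lx[i] = lat(i, 0); ly[i] = lat(i, 1);
  }
  long step = 0;
  for (int ph = 0; ph < phases.nrow(); ++ph) {
    const long t_max = (long) phases(ph, 0);
    const double a0 = phases(ph, 1), a1 = phases(ph, 2);
    const double s0 = phases(ph, 3), s1 = phases(ph, 4);
    for (long t = 0; t < t_max; ++t, ++step) {
      const double frac = (t_max > 1) ? (double) t / (double) (t_max - 1) : 0.0;
      const double alpha = a0 + (a1 - a0) * frac;
      const double sigma = s0 + (s1 - s0) * frac;
      int r = (int) (unif_rand() * n);
      if (r >= n) r = n - 1;
      const double *x = &xs[(size_t) r * k];
      // winner: smallest Euclidean distance, ties to lowest index
      int c = 0; double best = R_PosInf;
      const double *m = &cb[0];
      for (int i = 0; i < N; ++i, m += k) {
        double d2 = 0.0;
        for (int j = 0; j < k; ++j) {
          const double d = x[j] - m[j];
          d2 += d * d;
        }
        if (d2 < best) { best = d2; c = i; }
      }
      const double cx = lx[c], cy = ly[c];
      const double cut2 = 9.0 * sigma * sigma;
      const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
      double *mi = &cb[0];
      for (int i = 0; i < N; ++i, mi += k) {
        const double dx = lx[i] - cx, dy = ly[i] - cy;
        const double ld2 = dx * dx + dy * dy;
        if (ld2 > cut2) continue;
        const double h = alpha * std::exp(-ld2 * inv2s2);
        for (int j = 0; j < k; ++j)
          mi[j] += h * (x[j] - mi[j]);
      }
      if ((step & 1023) == 0) {
        for (int j = 0; j < k; ++j)
          if (!std::isfinite(cb[(size_t) c * k + j]))
            stop("non-finite codebook value at training step %ld", step);
      }
    }
  }
  NumericMatrix out(N, k);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < k; ++j) {
      const double v = cb[(size_t) i * k + j];
      if (!std::isfinite(v))
        stop("non-finite codebook value after training");
      out(i, j) = v;
    }
  return out;
}

// IDW with a per-cell partial sort for the m nearest observations.
// [[Rcpp::export]]
NumericVector idw_cpp(NumericVector cx, NumericVector cy,
                      NumericVector px, NumericVector py,
                      NumericVector pv, double power, int m) {
  const int nc = cx.size(), np = px.size();
  NumericVector out(nc);
  std::vector<std::pair<double, int> > d(np);
  for (int c = 0; c < nc; ++c) {
    int hit = -1;
    for (int p = 0; p < np; ++p) {
      const double dx = cx[c] - px[p], dy = cy[c] - py[p];
      const double dist = std::sqrt(dx * dx + dy * dy);
      if (dist < 1e-9 && hit < 0) hit = p;
      d[p] = std::make_pair(dist, p);
    }
    if (hit >= 0) { out[c] = pv[hit]; continue; }
    const int mm = std::min(m, np);
    std::partial_sort(d.begin(), d.begin() + mm, d.end());
    double wsum = 0.0, vsum = 0.0;
    for (int i = 0; i < mm; ++i) {
      const double w = std::pow(d[i].first, -power);
      wsum += w;
      vsum += w * pv[d[i].second];
    }
    out[c] = vsum / wsum;
  }
  return out;
}

// Winner node (0-based) and distance for each input row.
// [[Rcpp::export]]
List bmu_cpp(NumericMatrix X, NumericMatrix M) {
  const int n = X.nrow(), k = X.ncol(), N = M.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int r = 0; r < n; ++r) {
    int c = 0; double best = R_PosInf;
    for (int i = 0; i < N; ++i) {
      double d2 = 0.0;
      for (int j = 0; j < k; ++j) {
        const double d = X(r, j) - M(i, j);
        d2 += d * d;
      }
      if (d2 < best) { best = d2; c = i; }
    }
    idx[r] = c;
    dist[r] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
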