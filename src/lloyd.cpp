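#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Lloyd iterations with deterministic tie-breaking (lowest centroid index)
// and empty-cluster re-seeding at the point farthest from the empty
// centroid (points that are sole members of their cluster are exempt).
// Stops when the assignment is unchanged, the largest centroid movement
// falls below tol (after a final assignment pass), or max_iter is reached.
// Data are copied into contiguous row-major buffers so the inner distance
// loop vectorizes.
// [[Rcpp::export(name = ".lloyd_cpp")]]
List lloyd_cpp(NumericMatrix X, NumericMatrix init, int max_iter, double tol) {
  const int n = X.nrow(), d = X.ncol(), k = init.nrow();
  std::vector<double> xr(static_cast<size_t>(n) * d);
  std::vector<double> cent(static_cast<size_t>(k) * d);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < d; ++m) xr[static_cast<size_t>(i) * d + m] = X(i, m);
  for (int j = 0; j < k; ++j)
    for (int m = 0; m < d; ++m) cent[static_cast<size_t>(j) * d + m] = init(j, m);

  std::vector<int> assign(n, -1), prev(n, -2), sizes(k, 0);
  std::vector<double> wss_trace;
  double wss = 0.0;
  bool converged = false;
  int iter = 0;

  auto sqd = [&](const double* a, const double* b) {
    double s = 0.0;
    for (int m = 0; m < d; ++m) { const double v = a[m] - b[m]; s += v * v; }
    return s;
  };

  // one assignment sweep (nearest centroid) + empty-cluster repair
  auto assign_step = [&]() -> double {
    std::fill(sizes.begin(), sizes.end(), 0);
    double total = 0.0;
    for (int i = 0; i < n; ++i) {
      const double* xi = &xr[static_cast<size_t>(i) * d];
      int best = 0;
      double bd = sqd(xi, &cent[0]);
      for (int j = 1; j < k; ++j) {
        const double dj = sqd(xi, &cent[static_cast<size_t>(j) * d]);
        if (dj < bd) { bd = dj; best = j; }
      }
      assign[i] = best;
      sizes[best] += 1;
      total += bd;
    }
    for (int j = 0; j < k; ++j) {
      if (sizes[j] > 0) continue;
      int far = -1;
      double fd = -1.0;
      for (int i = 0; i < n; ++i) {
        if (sizes[assign[i]] <= 1) continue;
        const double di = sqd(&xr[static_cast<size_t>(i) * d],
                              &cent[static_cast<size_t>(j) * d]);
        if (di > fd) { fd = di; far = i; }
      }
      if (far < 0) continue;  // nothing movable; leave empty
      total -= sqd(&xr[static_cast<size_t>(far) * d],
                   &cent[static_cast<size_t>(assign[far]) * d]);
      sizes[assign[far]] -= 1;
      for (int m = 0; m < d; ++m)
        cent[static_cast<size_t>(j) * d + m] = xr[static_cast<size_t>(far) * d + m];
      assign[far] = j;
      sizes[j] = 1;  // its own position, distance 0
    }
    return total;
  };

  std::vector<double> nc(static_cast<size_t>(k) * d);
  for (iter = 1; iter <= max_iter; ++iter) {
    wss = assign_step();
    wss_trace.push_back(wss);
    if (iter > 1 && assign == prev) { converged = true; break; }
    prev = assign;
    // update step: centroid <- mean of assigned points
    std::fill(nc.begin(), nc.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double* cj = &nc[static_cast<size_t>(assign[i]) * d];
      const double* xi = &xr[static_cast<size_t>(i) * d];
      for (int m = 0; m < d; ++m) cj[m] += xi[m];
    }
    double move = 0.0;
    for (int j = 0; j < k; ++j) {
      if (sizes[j] == 0) continue;
      double mj = 0.0;
      double* cj = &cent[static_cast<size_t>(j) * d];
      double* nj = &nc[static_cast<size_t>(j) * d];
      for (int m = 0; m < d; ++m) {
        nj[m] /= sizes[j];
        const double v = nj[m] - cj[m];
        mj += v * v;
        cj[m] = nj[m];
      }
      if (mj > move) move = mj;
    }
    if (std::sqrt(move) < tol) {
      wss = assign_step();
      wss_trace.push_back(wss);
      converged = true;
      break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  NumericMatrix cent_out(k, d);
  for (int j = 0; j < k; ++j)
    for (int m = 0; m < d; ++m) cent_out(j, m) = cent[static_cast<size_t>(j) * d + m];
  return List::create(
    _["centroids"] = cent_out,
    _["assignment"] = IntegerVector(assign.begin(), assign.end()),
    _["wss"] = wss,
    _["iterations"] = iter,
    _["converged"] = converged,
    _["wss_trace"] = NumericVector(wss_trace.begin(), wss_trace.end()));
}
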