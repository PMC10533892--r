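#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Running min/max over a centered window of half-width w along a vector,
// ignoring positions outside the data (van Herk / Gil-Werman two-pass).
static void run_extreme(const double* x, double* out, int n, int w, bool take_min) {
  std::deque<int> dq;
  int lead = 0;
  for (int i = 0; i < n; ++i) {
    int hi = i + w; // newest index entering the window of position i
    while (lead <= hi && lead < n) {
      while (!dq.empty() &&
             (take_min ? x[dq.back()] >= x[lead] : x[dq.back()] <= x[lead]))
        dq.pop_back();
      dq.push_back(lead);
      ++lead;
    }
    while (!dq.empty() && dq.front() < i - w) dq.pop_front();
    out[i] = x[dq.front()];
  }
}

// Grayscale erosion (min) or dilation (max) with a disk structuring element.
// Pixels outside the image are ignored (treated as neutral), so a constant
// image maps to itself.
// [[Rcpp::export]]
NumericMatrix disk_filter_cpp(NumericMatrix img, int radius, bool take_min) {
  int nr = img.nrow(), nc = img.ncol();
  // Row-direction pass cache: for each needed half-width, min-filter each row.
  // Disk offsets: for |dy| <= r, half-width wx = floor(sqrt(r^2 - dy^2)).
  std::vector<int> wx(radius + 1);
  for (int dy = 0; dy <= radius; ++dy)
    wx[dy] = (int)std::floor(std::sqrt((double)radius * radius - (double)dy * dy));

  NumericMatrix out(nr, nc);
  double init = take_min ? R_PosInf : R_NegInf;
  std::fill(out.begin(), out.end(), init);

  // Cache row-filtered images by half-width (widths repeat across dy).
  std::map<int, NumericMatrix> cache;
  std::vector<double> buf(nc), obuf(nc);
  for (int dy = 0; dy <= radius; ++dy) {
    if (cache.find(wx[dy]) != cache.end()) continue;
    NumericMatrix rowf(nr, nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) buf[j] = img(i, j);
      run_extreme(buf.data(), obuf.data(), nc, wx[dy], take_min);
      for (int j = 0; j < nc; ++j) rowf(i, j) = obuf[j];
    }
    cache.emplace(wx[dy], rowf);
  }
  for (int dy = -radius; dy <= radius; ++dy) {
    NumericMatrix& rowf = cache[wx[std::abs(dy)]];
    for (int i = 0; i < nr; ++i) {
      int src = i + dy;
      if (src < 0 || src >= nr) continue;
      for (int j = 0; j < nc; ++j) {
        double v = rowf(src, j);
        if (take_min ? v < out(i, j) : v > out(i, j)) out(i, j) = v;
      }
    }
  }
  return out;
}

// Separable Gaussian convolution with reflective boundaries.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  auto reflect = [](int i, int n) {
    // symmetric half-sample reflection: -1 -> 0, n -> n-1
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  };

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * img(i, reflect(j + d, nc));
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(reflect(i + d, nr), j);
      out(i, j) = acc;
    }
  return out;
}

// 8-connected component labeling of a logical mask. Labels are 1..K in
// raster-scan discovery order; background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  const int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int d = 0; d < 8; ++d) {
          int ni = p.first + di[d], nj = p.second + dj[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(std::make_pair(ni, nj));
          }
        }
      }
    }
  }
  return lab;
}

// RSS of the plateau-then-decay model at fixed (t0, K), with plateau and
// baseline solved by the conditional 2x2 normal equations (baseline >= 0).
// When fixed_baseline is finite the asymptote is held there and only the
// plateau is solved; otherwise both are free (baseline clamped at 0).
// [[Rcpp::export]]
double plateau_rss_cpp(NumericVector t, NumericVector y, double t0, double K,
                       double fixed_baseline = NA_REAL) {
  int n = t.size();
  double suu = 0, svv = 0, suv = 0, suy = 0, svy = 0;
  for (int i = 0; i < n; ++i) {
    double e = (t[i] <= t0) ? 1.0 : std::exp(-K * (t[i] - t0) / 60.0);
    double v = 1.0 - e;
    suu += e * e; svv += v * v; suv += e * v;
    suy += e * y[i]; svy += v * y[i];
  }
  double plateau, baseline;
  if (R_finite(fixed_baseline)) {
    baseline = fixed_baseline;
    plateau = (suy - baseline * suv) / suu;
  } else {
    double det = suu * svv - suv * suv;
    if (det > 1e-12 * suu * std::max(svv, 1e-300)) {
      plateau = (suy * svv - svy * suv) / det;
      baseline = (svy * suu - suy * suv) / det;
    } else {
      plateau = suy / suu;
      baseline = 0.0;
    }
    if (baseline < 0) { baseline = 0.0; plateau = suy / suu; }
  }
  double rss = 0;
  for (int i = 0; i < n; ++i) {
    double e = (t[i] <= t0) ? 1.0 : std::exp(-K * (t[i] - t0) / 60.0);
    double f = plateau * e + baseline * (1.0 - e);
    rss += (y[i] - f) * (y[i] - f);
  }
  return rss;
}
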