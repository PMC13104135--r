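#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Bilinear sample of `img` at 0-based (qr, qc) coordinates, replicate border.
// qr/qc have the shape of the output.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_sample(const NumericMatrix& img,
                                  const NumericMatrix& qr,
                                  const NumericMatrix& qc) {
  const int h = img.nrow(), w = img.ncol();
  const int oh = qr.nrow(), ow = qr.ncol();
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j) {
    for (int i = 0; i < oh; ++i) {
      double r = clampd(qr(i, j), 0.0, h - 1.0);
      double c = clampd(qc(i, j), 0.0, w - 1.0);
      int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
      int r1 = r0 + 1 < h ? r0 + 1 : r0;
      int c1 = c0 + 1 < w ? c0 + 1 : c0;
      double fr = r - r0, fc = c - c0;
      double v00 = img(r0, c0), v01 = img(r0, c1);
      double v10 = img(r1, c0), v11 = img(r1, c1);
      out(i, j) = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                  fr * ((1 - fc) * v10 + fc * v11);
    }
  }
  return out;
}

// Separable convolution with a symmetric 1D kernel (length 2r+1), replicate
// boundary. Applied along rows then columns.
// [[Rcpp::export]]
NumericMatrix cpp_sepconv(const NumericMatrix& img, const NumericVector& k) {
  const int h = img.nrow(), w = img.ncol();
  const int n = k.size();
  const int r = (n - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // along columns (vertical, varying row index)
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
        acc += k[t + r] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // along rows (horizontal, varying column index)
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj >= w) jj = w - 1;
        acc += k[t + r] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Linearized brightness-constancy + quadratic smoothness increment solve:
//   min sum (Ix du + Iy dv + It)^2 + alpha2 (|grad du|^2 + |grad dv|^2)
// Coupled Gauss-Seidel with over-relaxation (lexicographic sweep order,
// fully deterministic), replicate boundary on the smoothness stencil.
// [[Rcpp::export]]
List cpp_hs_solve(const NumericMatrix& Ix, const NumericMatrix& Iy,
                  const NumericMatrix& It, double alpha2, int niter,
                  double omega = 1.9) {
  const int h = Ix.nrow(), w = Ix.ncol();
  NumericMatrix u(h, w), v(h, w);
  for (int it = 0; it < niter; ++it) {
    for (int j = 0; j < w; ++j) {
      int jl = j > 0 ? j - 1 : 0, jr = j < w - 1 ? j + 1 : w - 1;
      for (int i = 0; i < h; ++i) {
        int iu = i > 0 ? i - 1 : 0, id = i < h - 1 ? i + 1 : h - 1;
        double ub = 0.25 * (u(iu, j) + u(id, j) + u(i, jl) + u(i, jr));
        double vb = 0.25 * (v(iu, j) + v(id, j) + v(i, jl) + v(i, jr));
        double ix = Ix(i, j), iy = Iy(i, j);
        double denom = alpha2 + ix * ix + iy * iy;
        double t = (ix * ub + iy * vb + It(i, j)) / denom;
        double un = ub - ix * t, vn = vb - iy * t;
        u(i, j) = (1.0 - omega) * u(i, j) + omega * un;
        v(i, j) = (1.0 - omega) * v(i, j) + omega * vn;
      }
    }
  }
  return List::create(_["du"] = u, _["dv"] = v);
}

// Bilateral filter: range weights computed on `guide` (expected in [0,1]),
// values taken from `img`. Square window of half-width `radius`.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(const NumericMatrix& img, const NumericMatrix& guide,
                            int radius, double sigma_s, double sigma_r) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  std::vector<double> sw((2 * radius + 1) * (2 * radius + 1));
  for (int dj = -radius; dj <= radius; ++dj)
    for (int di = -radius; di <= radius; ++di)
      sw[(di + radius) + (dj + radius) * (2 * radius + 1)] =
        std::exp(-(di * di + dj * dj) / (2.0 * sigma_s * sigma_s));
  const double inv2sr2 = 1.0 / (2.0 * sigma_r * sigma_r);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double g0 = guide(i, j);
      double acc = 0.0, wsum = 0.0;
      for (int dj = -radius; dj <= radius; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= w) jj = w - 1;
        for (int di = -radius; di <= radius; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
          double dgr = guide(ii, jj) - g0;
          double wt = sw[(di + radius) + (dj + radius) * (2 * radius + 1)] *
                      std::exp(-dgr * dgr * inv2sr2);
          acc += wt * img(ii, jj);
          wsum += wt;
        }
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}

// Greedy non-maximum suppression: points must be pre-sorted by descending
// score; keeps a point if no already-kept point lies within `radius`
// (Euclidean). Returns 1-based indices of kept points, at most max_n.
// [[Rcpp::export]]
IntegerVector cpp_nms(const NumericVector& rows, const NumericVector& cols,
                      double radius, int max_n) {
  const int n = rows.size();
  const double r2 = radius * radius;
  std::vector<int> keep;
  keep.reserve(max_n > 0 ? max_n : 64);
  for (int i = 0; i < n; ++i) {
    bool ok = true;
    for (size_t k = 0; k < keep.size(); ++k) {
      double dr = rows[i] - rows[keep[k]];
      double dc = cols[i] - cols[keep[k]];
      if (dr * dr + dc * dc < r2) { ok = false; break; }
    }
    if (ok) {
      keep.push_back(i);
      if (max_n > 0 && (int)keep.size() >= max_n) break;
    }
  }
  IntegerVector out(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) out[k] = keep[k] + 1;
  return out;
}

// Hysteresis thresholding: flood weak pixels (8-connected) reachable from
// strong pixels.
// [[Rcpp::export]]
LogicalMatrix cpp_hysteresis(const LogicalMatrix& strong,
                             const LogicalMatrix& weak) {
  const int h = strong.nrow(), w = strong.ncol();
  LogicalMatrix out(h, w);
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (strong(i, j) && !out(i, j)) {
        out(i, j) = true;
        stack.push_back(std::make_pair(i, j));
      }
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    for (int dj = -1; dj <= 1; ++dj) {
      int jj = p.second + dj;
      if (jj < 0 || jj >= w) continue;
      for (int di = -1; di <= 1; ++di) {
        int ii = p.first + di;
        if (ii < 0 || ii >= h) continue;
        if (weak(ii, jj) && !out(ii, jj)) {
          out(ii, jj) = true;
          stack.push_back(std::make_pair(ii, jj));
        }
      }
    }
  }
  return out;
}

// Binary dilation by a disk of radius r (r = 0 returns input copy).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disk(const LogicalMatrix& mask, int r) {
  const int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix out(h, w);
  if (r <= 0) {
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) out(i, j) = mask(i, j);
    return out;
  }
  const int r2 = r * r;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) continue;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= w) continue;
        for (int di = -r; di <= r; ++di) {
          if (di * di + dj * dj > r2) continue;
          int ii = i + di;
          if (ii < 0 || ii >= h) continue;
          out(ii, jj) = true;
        }
      }
    }
  return out;
}
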