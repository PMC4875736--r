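// Compiled kernels for the two inner loops of the registration pipeline:
// the rigid bilinear warp applied at every fine-stage iteration, and the
// Lucas-Kanade window solve over all tracking points. Semantics mirror the
// R definitions exactly (same border, mask and conditioning rules).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resample `frame` under the rigid transform mapping reference coords to
// moving coords: out(x) = frame(R(phi)(x - c) + c + t), bilinear, 0-fill.
// A warped pixel is valid when its source position is in bounds and (if a
// mask is given) all four source neighbours are valid.
// [[Rcpp::export(name = ".warp_rigid_cpp")]]
List warp_rigid_cpp(NumericMatrix frame, double tx, double ty,
                    double phi_deg, Nullable<LogicalMatrix> mask_) {
  const int h = frame.nrow(), w = frame.ncol();
  const double cx = (w - 1.0) / 2.0, cy = (h - 1.0) / 2.0;
  const double a = phi_deg * M_PI / 180.0, ca = std::cos(a), sa = std::sin(a);
  NumericMatrix out(h, w);
  LogicalMatrix ok(h, w);
  const bool has_mask = mask_.isNotNull();
  LogicalMatrix mask;
  if (has_mask) mask = LogicalMatrix(mask_);
  for (int c = 0; c < w; ++c) {
    const double xr = c - cx;
    for (int r = 0; r < h; ++r) {
      const double yr = r - cy;
      const double sx = ca * xr - sa * yr + cx + tx;
      const double sy = sa * xr + ca * yr + cy + ty;
      if (sx < 0 || sx > w - 1 || sy < 0 || sy > h - 1) {
        out(r, c) = 0.0;
        ok(r, c) = false;
        continue;
      }
      const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      const int x1 = x0 < w - 1 ? x0 + 1 : x0;
      const int y1 = y0 < h - 1 ? y0 + 1 : y0;
      const double fx = sx - x0, fy = sy - y0;
      out(r, c) = (1 - fx) * (1 - fy) * frame(y0, x0) +
                  fx * (1 - fy) * frame(y0, x1) +
                  (1 - fx) * fy * frame(y1, x0) +
                  fx * fy * frame(y1, x1);
      ok(r, c) = has_mask
        ? (mask(y0, x0) && mask(y0, x1) && mask(y1, x0) && mask(y1, x1))
        : true;
    }
  }
  return List::create(_["image"] = out, _["mask"] = ok);
}

static inline double grad_x(const NumericMatrix &m, int r, int c) {
  const int w = m.ncol();
  const int cl = c > 0 ? c - 1 : 0, cr = c < w - 1 ? c + 1 : w - 1;
  return (m(r, cr) - m(r, cl)) / 2.0;
}

static inline double grad_y(const NumericMatrix &m, int r, int c) {
  const int h = m.nrow();
  const int ru = r > 0 ? r - 1 : 0, rd = r < h - 1 ? r + 1 : h - 1;
  return (m(rd, c) - m(ru, c)) / 2.0;
}

// Lucas-Kanade normal-equation solve over an M x M window at each tracking
// point (0-based integer coordinates, window fully inside the image).
// Temporal difference D = mov - ref; spatial gradients of mov by central
// differences. Returns (dx, dy, lost): lost when the window touches an
// invalid pixel, the structure matrix is ill-conditioned, or |d| > M/2.
// [[Rcpp::export(name = ".lk_solve_cpp")]]
DataFrame lk_solve_cpp(NumericMatrix ref, NumericMatrix mov,
                       IntegerVector px, IntegerVector py, int window,
                       Nullable<LogicalMatrix> mask_) {
  const int n = px.size();
  const int hw = (window - 1) / 2;
  const bool has_mask = mask_.isNotNull();
  LogicalMatrix mask;
  if (has_mask) mask = LogicalMatrix(mask_);
  NumericVector dx(n, NA_REAL), dy(n, NA_REAL);
  LogicalVector lost(n, true);
  const double eps = std::numeric_limits<double>::epsilon();
  for (int j = 0; j < n; ++j) {
    const int x = px[j], y = py[j];
    bool valid = true;
    if (has_mask) {
      for (int c = x - hw; c <= x + hw && valid; ++c)
        for (int r = y - hw; r <= y + hw; ++r)
          if (!mask(r, c)) { valid = false; break; }
    }
    if (!valid) continue;
    double gxx = 0, gxy = 0, gyy = 0, bx = 0, by = 0;
    for (int c = x - hw; c <= x + hw; ++c) {
      for (int r = y - hw; r <= y + hw; ++r) {
        const double ix = grad_x(mov, r, c);
        const double iy = grad_y(mov, r, c);
        const double d = mov(r, c) - ref(r, c);
        gxx += ix * ix; gxy += ix * iy; gyy += iy * iy;
        bx -= d * ix; by -= d * iy;
      }
    }
    const double det = gxx * gyy - gxy * gxy;
    const double tr = gxx + gyy;
    const double disc = tr * tr / 4.0 - det;
    const double lam_min = tr / 2.0 - std::sqrt(disc > 0 ? disc : 0);
    if (det <= eps || lam_min <= 1e-10 * window * window) continue;
    const double ddx = (gyy * bx - gxy * by) / det;
    const double ddy = (gxx * by - gxy * bx) / det;
    dx[j] = ddx; dy[j] = ddy;
    lost[j] = std::sqrt(ddx * ddx + ddy * ddy) > window / 2.0;
  }
  return DataFrame::create(_["dx"] = dx, _["dy"] = dy, _["lost"] = lost);
}

// Raw trackability Q at the solved displacement:
// Q = sum((D + Ix dx + Iy dy)(Ix + Iy)) / (2 M^2) over the window.
// [[Rcpp::export(name = ".lk_q_cpp")]]
NumericVector lk_q_cpp(NumericMatrix ref, NumericMatrix mov,
                       IntegerVector px, IntegerVector py,
                       NumericVector dx, NumericVector dy, int window) {
  const int n = px.size();
  const int hw = (window - 1) / 2;
  NumericVector q(n, NA_REAL);
  for (int j = 0; j < n; ++j) {
    if (NumericVector::is_na(dx[j])) continue;
    const int x = px[j], y = py[j];
    double acc = 0;
    for (int c = x - hw; c <= x + hw; ++c) {
      for (int r = y - hw; r <= y + hw; ++r) {
        const double ix = grad_x(mov, r, c);
        const double iy = grad_y(mov, r, c);
        const double d = mov(r, c) - ref(r, c);
        acc += (d + ix * dx[j] + iy * dy[j]) * (ix + iy);
      }
    }
    q[j] = acc / (2.0 * window * window);
  }
  return q;
}
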