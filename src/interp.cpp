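// Scattered-to-grid interpolation and Voronoi rendering helpers.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Moving-least-squares (weighted local-linear) interpolation of scattered
// samples at query points.  First-order accurate for smooth fields, like
// barycentric interpolation on a triangulation; queries farther than max_r
// from their nearest sample return 0 (outside the sampled hull).
// [[Rcpp::export]]
NumericVector cpp_mls_interp(NumericVector sx, NumericVector sy, NumericVector sv,
                             NumericVector qx, NumericVector qy, int k, double h,
                             double max_r) {
  int ns = sx.size(), nq = qx.size();
  // bucket grid over the samples
  double lox = 1e300, loy = 1e300, hix = -1e300, hiy = -1e300;
  for (int i = 0; i < ns; ++i) {
    lox = std::min(lox, (double)sx[i]); hix = std::max(hix, (double)sx[i]);
    loy = std::min(loy, (double)sy[i]); hiy = std::max(hiy, (double)sy[i]);
  }
  double cell = std::max(h, 1e-9);
  int gx = std::max(1, (int)std::ceil((hix - lox) / cell) + 1);
  int gy = std::max(1, (int)std::ceil((hiy - loy) / cell) + 1);
  gx = std::min(gx, 2048); gy = std::min(gy, 2048);
  double cw = std::max((hix - lox) / gx, 1e-12), ch = std::max((hiy - loy) / gy, 1e-12);
  std::vector<std::vector<int>> buckets((size_t)gx * gy);
  for (int i = 0; i < ns; ++i) {
    int ix = std::min(gx - 1, std::max(0, (int)((sx[i] - lox) / cw)));
    int iy = std::min(gy - 1, std::max(0, (int)((sy[i] - loy) / ch)));
    buckets[(size_t)iy * gx + ix].push_back(i);
  }
  NumericVector out(nq);
  std::vector<std::pair<double, int>> cand;
  for (int q = 0; q < nq; ++q) {
    double x = qx[q], y = qy[q];
    int ix = std::min(gx - 1, std::max(0, (int)((x - lox) / cw)));
    int iy = std::min(gy - 1, std::max(0, (int)((y - loy) / ch)));
    cand.clear();
    // expand rings until enough candidates (or the whole grid is covered)
    int ring = 0, maxring = std::max(gx, gy);
    while ((int)cand.size() < k && ring <= maxring) {
      int x0 = std::max(0, ix - ring), x1 = std::min(gx - 1, ix + ring);
      int y0 = std::max(0, iy - ring), y1 = std::min(gy - 1, iy + ring);
      for (int by = y0; by <= y1; ++by)
        for (int bx = x0; bx <= x1; ++bx) {
          if (ring > 0 && bx > x0 && bx < x1 && by > y0 && by < y1) continue; // interior done
          for (int i : buckets[(size_t)by * gx + bx]) {
            double dx = sx[i] - x, dy = sy[i] - y;
            cand.push_back({dx * dx + dy * dy, i});
          }
        }
      ++ring;
    }
    // one extra ring so that the k nearest are exact
    {
      int x0 = std::max(0, ix - ring), x1 = std::min(gx - 1, ix + ring);
      int y0 = std::max(0, iy - ring), y1 = std::min(gy - 1, iy + ring);
      for (int by = y0; by <= y1; ++by)
        for (int bx = x0; bx <= x1; ++bx) {
          if (bx > x0 && bx < x1 && by > y0 && by < y1) continue;
          for (int i : buckets[(size_t)by * gx + bx]) {
            double dx = sx[i] - x, dy = sy[i] - y;
            cand.push_back({dx * dx + dy * dy, i});
          }
        }
    }
    if (cand.empty()) { out[q] = 0.0; continue; }
    int kk = std::min((int)cand.size(), k);
    std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
    if (std::sqrt(cand[0].first) > max_r) { out[q] = 0.0; continue; }
    // weighted linear fit v ~ a + b dx + c dy
    double sw = 0, swx = 0, swy = 0, swxx = 0, swxy = 0, swyy = 0, swv = 0, swvx = 0, swvy = 0;
    for (int j = 0; j < kk; ++j) {
      int i = cand[j].second;
      double dx = sx[i] - x, dy = sy[i] - y;
      double w = 1.0 / (cand[j].first + 1e-6 * h * h);
      sw += w; swx += w * dx; swy += w * dy;
      swxx += w * dx * dx; swxy += w * dx * dy; swyy += w * dy * dy;
      swv += w * sv[i]; swvx += w * sv[i] * dx; swvy += w * sv[i] * dy;
    }
    // solve normal equations (3x3) by Cramer; fall back to weighted mean
    double A[3][3] = { { sw, swx, swy }, { swx, swxx, swxy }, { swy, swxy, swyy } };
    double B[3] = { swv, swvx, swvy };
    double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
               - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
               + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
    if (std::fabs(det) < 1e-12 * std::max(1.0, sw * sw * sw) || kk < 3) {
      out[q] = swv / sw;
    } else {
      double a0 = (B[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
                 - A[0][1] * (B[1] * A[2][2] - A[1][2] * B[2])
                 + A[0][2] * (B[1] * A[2][1] - A[1][1] * B[2])) / det;
      out[q] = a0;
    }
  }
  return out;
}

// Nearest-seed label for every pixel inside the calibrated image circle;
// 0 outside the circle.  Seeds are pixel coordinates (1-based R convention).
// [[Rcpp::export]]
IntegerMatrix cpp_voronoi_label(NumericMatrix seeds, int nx, int ny,
                                double cx, double cy, double radius) {
  IntegerMatrix out(ny, nx);   // row = y, col = x (image matrix convention)
  int ns = seeds.nrow();
  double r2 = radius * radius;
  for (int x = 1; x <= nx; ++x) {
    for (int y = 1; y <= ny; ++y) {
      double dx = x - cx, dy = y - cy;
      if (dx * dx + dy * dy > r2) { out(y - 1, x - 1) = 0; continue; }
      double best = 1e300; int bi = 0;
      for (int s = 0; s < ns; ++s) {
        double ex = seeds(s, 0) - x, ey = seeds(s, 1) - y;
        double d2 = ex * ex + ey * ey;
        if (d2 < best) { best = d2; bi = s + 1; }
      }
      out(y - 1, x - 1) = bi;
    }
  }
  return out;
}
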