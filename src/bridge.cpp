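#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate the time-integrated Brownian-bridge position density of a track
// on a regular grid. For each segment between consecutive fixes i, i+1 the
// position at interior time fraction alpha is bivariate normal with mean
// z_i + alpha * (z_{i+1} - z_i) and isotropic variance
//   T * alpha * (1 - alpha) * sigma2_seg + (1-alpha)^2 * delta_i^2
//     + alpha^2 * delta_{i+1}^2,
// integrated over alpha by midpoint quadrature and weighted by the segment
// duration T. Gaussians are truncated at 6 SD; the caller renormalizes.
//
// Grid cells are centred at x0 + (ix + 0.5) * cell, ix = 0..nx-1 (same for y).

// [[Rcpp::export]]
NumericMatrix bridge_ud_cpp(NumericVector t, NumericVector x, NumericVector y,
                            NumericVector delta, NumericVector sigma2,
                            double x0, double y0, double cell,
                            int nx, int ny, int nquad) {
  const int k = t.size();
  NumericMatrix z(nx, ny);
  if (k == 0) return z;

  auto stamp = [&](double mx, double my, double var, double w) {
    const double sd = std::sqrt(var);
    const double lim = 6.0 * sd;
    int ix0 = std::max(0, (int)std::floor((mx - lim - x0) / cell - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((mx + lim - x0) / cell - 0.5));
    int iy0 = std::max(0, (int)std::floor((my - lim - y0) / cell - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((my + lim - y0) / cell - 0.5));
    if (ix1 < ix0 || iy1 < iy0) return;
    const double norm = w * cell * cell / (2.0 * M_PI * var);
    const double inv2v = 1.0 / (2.0 * var);
    for (int ix = ix0; ix <= ix1; ++ix) {
      const double dx = x0 + (ix + 0.5) * cell - mx;
      const double ex = dx * dx;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = y0 + (iy + 0.5) * cell - my;
        z(ix, iy) += norm * std::exp(-(ex + dy * dy) * inv2v);
      }
    }
  };

  if (k == 1) {
    double var = std::max(delta[0] * delta[0], 1e-6);
    stamp(x[0], y[0], var, 1.0);
    return z;
  }

  for (int i = 0; i < k - 1; ++i) {
    const double T = t[i + 1] - t[i];
    if (T <= 0) continue;
    const double s2 = 0.5 * (sigma2[i] + sigma2[i + 1]);
    const double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i];
    const double w = T / nquad;
    for (int q = 0; q < nquad; ++q) {
      const double alpha = (q + 0.5) / nquad;
      const double var = std::max(
          T * alpha * (1.0 - alpha) * s2 +
              (1.0 - alpha) * (1.0 - alpha) * delta[i] * delta[i] +
              alpha * alpha * delta[i + 1] * delta[i + 1],
          1e-6);
      stamp(x[i] + alpha * dx, y[i] + alpha * dy, var, w);
    }
  }
  return z;
}

// Weighted nonlinear least-squares trilateration: minimise
//   sum_j w_j * (||p - r_j|| - dhat_j)^2
// over p = (x, y) by Levenberg-Marquardt damped Gauss-Newton.

// [[Rcpp::export]]
List trilaterate_cpp(NumericVector rx, NumericVector ry, NumericVector dhat,
                     NumericVector w, double x0, double y0,
                     int max_iter = 50, double tol = 1e-6) {
  const int n = rx.size();
  double x = x0, y = y0, lambda = 1e-3;
  auto rss_at = [&](double px, double py) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      double d = std::hypot(px - rx[j], py - ry[j]);
      double e = d - dhat[j];
      s += w[j] * e * e;
    }
    return s;
  };
  double rss = rss_at(x, y);
  int it = 0;
  bool converged = false;
  for (it = 0; it < max_iter; ++it) {
    // J^T W J (2x2) and J^T W e (2)
    double a11 = 0, a12 = 0, a22 = 0, g1 = 0, g2 = 0;
    for (int j = 0; j < n; ++j) {
      double dx = x - rx[j], dy = y - ry[j];
      double d = std::max(std::hypot(dx, dy), 1e-9);
      double e = d - dhat[j];
      double jx = dx / d, jy = dy / d;
      a11 += w[j] * jx * jx;
      a12 += w[j] * jx * jy;
      a22 += w[j] * jy * jy;
      g1 += w[j] * jx * e;
      g2 += w[j] * jy * e;
    }
    bool stepped = false;
    for (int tries = 0; tries < 20; ++tries) {
      double b11 = a11 + lambda * std::max(a11, 1e-12);
      double b22 = a22 + lambda * std::max(a22, 1e-12);
      double det = b11 * b22 - a12 * a12;
      if (std::fabs(det) < 1e-300) { lambda *= 10; continue; }
      double sx = -(b22 * g1 - a12 * g2) / det;
      double sy = -(-a12 * g1 + b11 * g2) / det;
      double nrss = rss_at(x + sx, y + sy);
      if (nrss <= rss) {
        x += sx; y += sy;
        double step = std::hypot(sx, sy);
        rss = nrss;
        lambda = std::max(lambda * 0.3, 1e-12);
        stepped = true;
        if (step < tol) converged = true;
        break;
      }
      lambda *= 10;
    }
    if (converged || !stepped) { converged = converged || !stepped; break; }
  }
  return List::create(_["x"] = x, _["y"] = y, _["rss"] = rss,
                      _["iterations"] = it, _["converged"] = converged);
}
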