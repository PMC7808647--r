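#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Flat-detector fan-beam geometry, all lengths in mm.
//
// Image convention: n x n matrix, column index ix <-> x (right), row index
// iy <-> y (up); pixel centre (x, y) = ((i + 0.5 - n/2) * h) for i = ix, iy.
// Source at view angle beta sits at R_s * (cos b, sin b); the detector line
// passes through -R_d * (cos b, sin b) with in-plane direction
// (-sin b, cos b).  Detector coordinate u is measured physically on the
// detector; bin j (0-based) has u = (j + 0.5 - n_bins/2) * cell.

struct Ray {
  double sx, sy;   // source
  double dx, dy;   // unit direction source -> detector bin
};

static inline Ray make_ray(double beta, double u, double r_src, double r_det) {
  const double cb = std::cos(beta), sb = std::sin(beta);
  Ray r;
  r.sx = r_src * cb;
  r.sy = r_src * sb;
  const double px = -r_det * cb - u * sb;
  const double py = -r_det * sb + u * cb;
  double vx = px - r.sx, vy = py - r.sy;
  const double len = std::sqrt(vx * vx + vy * vy);
  r.dx = vx / len;
  r.dy = vy / len;
  return r;
}

// Joseph (ray-driven, bilinear) line integral of the image along one ray.
static double joseph_forward(const double* img, int n, double h, const Ray& r) {
  double acc = 0.0;
  if (std::fabs(r.dx) >= std::fabs(r.dy)) {
    // step across x (column) planes, interpolate along y (rows)
    const double step = h / std::fabs(r.dx);
    for (int ix = 0; ix < n; ++ix) {
      const double x = (ix + 0.5 - n / 2.0) * h;
      const double t = (x - r.sx) / r.dx;
      const double y = r.sy + t * r.dy;
      const double ry = y / h + n / 2.0 - 0.5;
      const int iy0 = (int)std::floor(ry);
      const double w = ry - iy0;
      double v = 0.0;
      if (iy0 >= 0 && iy0 < n)       v += (1.0 - w) * img[iy0 + (size_t)ix * n];
      if (iy0 + 1 >= 0 && iy0 + 1 < n) v += w * img[iy0 + 1 + (size_t)ix * n];
      acc += v;
    }
    return acc * step;
  } else {
    const double step = h / std::fabs(r.dy);
    for (int iy = 0; iy < n; ++iy) {
      const double y = (iy + 0.5 - n / 2.0) * h;
      const double t = (y - r.sy) / r.dy;
      const double x = r.sx + t * r.dx;
      const double rx = x / h + n / 2.0 - 0.5;
      const int ix0 = (int)std::floor(rx);
      const double w = rx - ix0;
      double v = 0.0;
      if (ix0 >= 0 && ix0 < n)       v += (1.0 - w) * img[iy + (size_t)ix0 * n];
      if (ix0 + 1 >= 0 && ix0 + 1 < n) v += w * img[iy + (size_t)(ix0 + 1) * n];
      acc += v;
    }
    return acc * step;
  }
}

// Scatter (exact transpose of joseph_forward) of one sinogram sample.
static void joseph_adjoint(double* img, int n, double h, const Ray& r,
                           double val) {
  if (std::fabs(r.dx) >= std::fabs(r.dy)) {
    const double step = h / std::fabs(r.dx);
    const double sv = val * step;
    for (int ix = 0; ix < n; ++ix) {
      const double x = (ix + 0.5 - n / 2.0) * h;
      const double t = (x - r.sx) / r.dx;
      const double y = r.sy + t * r.dy;
      const double ry = y / h + n / 2.0 - 0.5;
      const int iy0 = (int)std::floor(ry);
      const double w = ry - iy0;
      if (iy0 >= 0 && iy0 < n)       img[iy0 + (size_t)ix * n] += (1.0 - w) * sv;
      if (iy0 + 1 >= 0 && iy0 + 1 < n) img[iy0 + 1 + (size_t)ix * n] += w * sv;
    }
  } else {
    const double step = h / std::fabs(r.dy);
    const double sv = val * step;
    for (int iy = 0; iy < n; ++iy) {
      const double y = (iy + 0.5 - n / 2.0) * h;
      const double t = (y - r.sy) / r.dy;
      const double x = r.sx + t * r.dx;
      const double rx = x / h + n / 2.0 - 0.5;
      const int ix0 = (int)std::floor(rx);
      const double w = rx - ix0;
      if (ix0 >= 0 && ix0 < n)       img[iy + (size_t)ix0 * n] += (1.0 - w) * sv;
      if (ix0 + 1 >= 0 && ix0 + 1 < n) img[iy + (size_t)(ix0 + 1) * n] += w * sv;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix image, double pixel_size,
                                  NumericVector angles, double r_src,
                                  double r_det, NumericVector u_centers) {
  const int n = image.nrow();
  if (image.ncol() != n) stop("image must be square");
  const int n_views = angles.size();
  const int n_bins = u_centers.size();
  NumericMatrix out(n_views, n_bins);
  const double* img = REAL(image);
  for (int v = 0; v < n_views; ++v) {
    const double beta = angles[v];
    for (int j = 0; j < n_bins; ++j) {
      Ray r = make_ray(beta, u_centers[j], r_src, r_det);
      out(v, j) = joseph_forward(img, n, pixel_size, r);
    }
  }
  return out;
}

// Unfiltered adjoint backprojection: exact transpose of cpp_forward_project.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_adjoint(NumericMatrix sino, int n,
                                      double pixel_size, NumericVector angles,
                                      double r_src, double r_det,
                                      NumericVector u_centers) {
  const int n_views = angles.size();
  const int n_bins = u_centers.size();
  if (sino.nrow() != n_views || sino.ncol() != n_bins)
    stop("sinogram shape inconsistent with angles/detector");
  NumericMatrix img(n, n);
  double* out = REAL(img);
  for (int v = 0; v < n_views; ++v) {
    const double beta = angles[v];
    for (int j = 0; j < n_bins; ++j) {
      const double s = sino(v, j);
      if (s == 0.0) continue;
      Ray r = make_ray(beta, u_centers[j], r_src, r_det);
      joseph_adjoint(out, n, pixel_size, r, s);
    }
  }
  return img;
}

// Pixel-driven distance-weighted backprojection of a ramp-filtered sinogram.
// fsino rows are views; columns are detector bins already referenced to the
// iso-centre scale: bin j has coordinate u0_iso + j * du_iso.  The weight is
// R_s^2 / (R_s - r_par)^2 with r_par the pixel coordinate along the central
// ray; the caller applies the d_beta / 2 view factor.
// [[Rcpp::export]]
NumericMatrix cpp_backproject_fbp(NumericMatrix fsino, NumericVector angles,
                                  double r_src, double u0_iso, double du_iso,
                                  int n, double pixel_size) {
  const int n_views = angles.size();
  const int n_bins = fsino.ncol();
  if (fsino.nrow() != n_views) stop("fsino rows must equal number of views");
  NumericMatrix img(n, n);
  double* out = REAL(img);
  const double* q = REAL(fsino);
  for (int v = 0; v < n_views; ++v) {
    const double cb = std::cos(angles[v]), sb = std::sin(angles[v]);
    const double* row = q + v;  // stride n_views along bins
    for (int ix = 0; ix < n; ++ix) {
      const double x = (ix + 0.5 - n / 2.0) * pixel_size;
      for (int iy = 0; iy < n; ++iy) {
        const double y = (iy + 0.5 - n / 2.0) * pixel_size;
        const double rpar = x * cb + y * sb;
        const double rperp = -x * sb + y * cb;
        const double tdist = r_src - rpar;
        if (tdist <= 1e-6) continue;
        const double u_iso = r_src * rperp / tdist;
        const double fj = (u_iso - u0_iso) / du_iso;
        const int j0 = (int)std::floor(fj);
        if (j0 < 0 || j0 + 1 >= n_bins) continue;
        const double w = fj - j0;
        const double val = (1.0 - w) * row[(size_t)j0 * n_views] +
                           w * row[(size_t)(j0 + 1) * n_views];
        const double uw = r_src / tdist;
        out[iy + (size_t)ix * n] += uw * uw * val;
      }
    }
  }
  return img;
}
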