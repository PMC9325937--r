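#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
// mirror boundary without edge repetition: ... 2 1 | 0 1 2 ... n-1 | n-2 ...
inline int mirror(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

void blur_axis(std::vector<double> &buf, std::vector<double> &tmp, int nx,
               int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (double &w : ker) w /= s;  // unit sum: conserves mean intensity

  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int lens[3] = {nx, ny, nz};
  const int n = lens[axis];
  const R_xlen_t st = strides[axis];
  int oa = (axis == 0) ? 1 : 0, ob = (axis == 2) ? 1 : 2;
  for (int b = 0; b < lens[ob]; ++b)
    for (int a = 0; a < lens[oa]; ++a) {
      R_xlen_t base = (R_xlen_t)a * strides[oa] + (R_xlen_t)b * strides[ob];
      for (int i = 0; i < n; ++i) tmp[i] = buf[base + st * i];
      for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int j = -rad; j <= rad; ++j)
          acc += ker[j + rad] * tmp[mirror(i + j, n)];
        buf[base + st * i] = acc;
      }
    }
}
}  // namespace

// Separable Gaussian blur with per-axis sigma in voxel units, mirror boundary.
//' @noRd
// [[Rcpp::export(name = ".gauss_blur_cpp")]]
NumericVector gauss_blur_cpp(NumericVector x, IntegerVector dim,
                             NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> buf(n), tmp(std::max(nx, std::max(ny, nz)));
  for (R_xlen_t i = 0; i < n; ++i) buf[i] = x[i];
  for (int ax = 0; ax < 3; ++ax) blur_axis(buf, tmp, nx, ny, nz, ax, sigma_vox[ax]);
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = buf[i];
  return out;
}

// Gradient magnitude by central differences (mirror boundary), spacing-aware.
//' @noRd
// [[Rcpp::export(name = ".gradient_mag_cpp")]]
NumericVector gradient_mag_cpp(NumericVector x, IntegerVector dim,
                               NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xx = 0; xx < nx; ++xx) {
        R_xlen_t i = (R_xlen_t)xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        double gx = (x[(R_xlen_t)mirror(xx + 1, nx) + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] -
                     x[(R_xlen_t)mirror(xx - 1, nx) + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)]) /
                    (2.0 * spacing[0]);
        double gy = (x[(R_xlen_t)xx + (R_xlen_t)nx * (mirror(y + 1, ny) + (R_xlen_t)ny * z)] -
                     x[(R_xlen_t)xx + (R_xlen_t)nx * (mirror(y - 1, ny) + (R_xlen_t)ny * z)]) /
                    (2.0 * spacing[1]);
        double gz = (x[(R_xlen_t)xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * mirror(z + 1, nz))] -
                     x[(R_xlen_t)xx + (R_xlen_t)nx * (y + (R_xlen_t)ny * mirror(z - 1, nz))]) /
                    (2.0 * spacing[2]);
        out[i] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

namespace {
// Keys cubic convolution kernel, a = -0.5 (exact for polynomials of degree
// <= 2 and for linear ramps at any sample phase)
inline void cubic_w(double t, double w[4]) {
  const double a = -0.5;
  double t2 = t * t, t3 = t2 * t;
  w[0] = a * (t3 - 2 * t2 + t);
  w[1] = (a + 2) * t3 - (a + 3) * t2 + 1;
  w[2] = -(a + 2) * t3 + (2 * a + 3) * t2 - a * t;
  w[3] = -a * (t3 - t2);
}

inline double sample1(const NumericVector &x, int nx, int ny, int nz, double u,
                      double v, double w, int order) {
  auto at = [&](int i, int j, int k) -> double {
    return x[(R_xlen_t)mirror(i, nx) +
             (R_xlen_t)nx * (mirror(j, ny) + (R_xlen_t)ny * mirror(k, nz))];
  };
  if (order == 0) {
    return at((int)std::floor(u + 0.5), (int)std::floor(v + 0.5),
              (int)std::floor(w + 0.5));
  }
  if (order == 1) {
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
    double fu = u - i0, fv = v - j0, fw = w - k0;
    double acc = 0;
    for (int dk = 0; dk <= 1; ++dk)
      for (int dj = 0; dj <= 1; ++dj)
        for (int di = 0; di <= 1; ++di) {
          double wt = (di ? fu : 1 - fu) * (dj ? fv : 1 - fv) * (dk ? fw : 1 - fw);
          if (wt != 0) acc += wt * at(i0 + di, j0 + dj, k0 + dk);
        }
    return acc;
  }
  // cubic
  int i0 = (int)std::floor(u), j0 = (int)std::floor(v), k0 = (int)std::floor(w);
  double wu[4], wv[4], ww[4];
  cubic_w(u - i0, wu);
  cubic_w(v - j0, wv);
  cubic_w(w - k0, ww);
  double acc = 0;
  for (int dk = 0; dk < 4; ++dk) {
    if (ww[dk] == 0) continue;
    for (int dj = 0; dj < 4; ++dj) {
      if (wv[dj] == 0) continue;
      double wjk = wv[dj] * ww[dk];
      for (int di = 0; di < 4; ++di)
        if (wu[di] != 0)
          acc += wu[di] * wjk * at(i0 - 1 + di, j0 - 1 + dj, k0 - 1 + dk);
    }
  }
  return acc;
}
}  // namespace

// Resample onto an output grid through an affine index map: the input voxel
// coordinate for output index (i,j,k) is A %*% c(i,j,k) + b (0-based voxel
// coordinates on both sides). order: 0 nearest, 1 trilinear, 3 cubic.
//' @noRd
// [[Rcpp::export(name = ".sample_affine_cpp")]]
NumericVector sample_affine_cpp(NumericVector x, IntegerVector dim_in,
                                NumericMatrix A, NumericVector b,
                                IntegerVector dim_out, int order) {
  const int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  const int mx = dim_out[0], my = dim_out[1], mz = dim_out[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  R_xlen_t p = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++p) {
        double u = A(0, 0) * i + A(0, 1) * j + A(0, 2) * k + b[0];
        double v = A(1, 0) * i + A(1, 1) * j + A(1, 2) * k + b[1];
        double w = A(2, 0) * i + A(2, 1) * j + A(2, 2) * k + b[2];
        out[p] = sample1(x, nx, ny, nz, u, v, w, order);
      }
  return out;
}
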