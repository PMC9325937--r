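#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform of a sampled function (Felzenszwalb &
// Huttenlocher), generalised to sample spacing h. f holds squared distances,
// d receives the lower envelope evaluated at the sample positions.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double h) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * h;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  // large finite sentinel: infinity breaks the envelope intersection
  // arithmetic (INF - INF) inside dt1d
  const double BIG = (double)nx * nx * spacing[0] * spacing[0] +
                     (double)ny * ny * spacing[1] * spacing[1] +
                     (double)nz * nz * spacing[2] * spacing[2] + 1.0;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t stz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * y;
      for (int z = 0; z < nz; ++z) f[z] = out[base + stz * z];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + stz * z] = d[z];
    }
  return out;
}

// Sphere-fitting local thickness on an isotropic grid. edt_sq_vox holds the
// squared distance (in voxel units) from each foreground voxel centre to the
// nearest background voxel centre; 0 marks background. The thickness at p is
// the diameter 2*r(q) of the largest sphere (centre q, radius r(q) = EDT(q))
// that covers p, coverage decided at voxel centres with ||p-q|| < r(q).
//' @noRd
// [[Rcpp::export(name = ".local_thickness_vox_cpp")]]
NumericVector local_thickness_vox_cpp(NumericVector edt_sq_vox,
                                      IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector th(n);

  // order foreground voxels by decreasing radius so each voxel is finalised
  // by the first (largest) sphere that covers it
  std::vector<R_xlen_t> idx;
  idx.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i)
    if (edt_sq_vox[i] > 0) idx.push_back(i);
  std::stable_sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    return edt_sq_vox[a] > edt_sq_vox[b];
  });

  for (R_xlen_t t = 0; t < (R_xlen_t)idx.size(); ++t) {
    R_xlen_t q = idx[t];
    double r2 = edt_sq_vox[q];
    double diam = 2.0 * std::sqrt(r2);
    int qx = (int)(q % nx);
    int qy = (int)((q / nx) % ny);
    int qz = (int)(q / ((R_xlen_t)nx * ny));
    int rr = (int)std::ceil(std::sqrt(r2));
    for (int dz = -rr; dz <= rr; ++dz) {
      int z = qz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dy = -rr; dy <= rr; ++dy) {
        int y = qy + dy;
        if (y < 0 || y >= ny) continue;
        double d2yz = (double)dz * dz + (double)dy * dy;
        if (d2yz >= r2) continue;
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int dx = -rr; dx <= rr; ++dx) {
          int x = qx + dx;
          if (x < 0 || x >= nx) continue;
          double d2 = d2yz + (double)dx * dx;
          if (d2 < r2 - 1e-9) {
            R_xlen_t p = base + x;
            if (th[p] < diam) th[p] = diam;
          }
        }
      }
    }
  }
  return th;
}
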