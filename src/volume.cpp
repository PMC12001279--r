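// 3D volume processing for nuclei detection: separable Gaussian smoothing,
// Hessian-based principal signal curvatures, blob score, 26-connected
// component centroids, and Gaussian blob rendering for the synthetic
// generator. Volumes are R arrays (column-major, dims nx x ny x nz).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
  return k;
}

static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void smooth_axis(std::vector<double>& v, std::vector<double>& tmp,
                        int nx, int ny, int nz, int axis,
                        const std::vector<double>& k) {
  int r = ((int)k.size() - 1) / 2;
  long sx = 1, sy = nx, sz = (long)nx * ny;
  if (axis == 0) {
    // contiguous lines along x
    long nlines = (long)ny * nz;
    for (long l = 0; l < nlines; ++l) {
      const double* src = &v[l * nx];
      double* dst = &tmp[l * nx];
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        if (i - r >= 0 && i + r < nx) {
          const double* L = src + (i - r);
          for (int q = 0; q < 2 * r + 1; ++q) acc += L[q] * k[q];
        } else {
          for (int q = -r; q <= r; ++q) acc += src[reflect(i + q, nx)] * k[q + r];
        }
        dst[i] = acc;
      }
    }
  } else {
    // y or z axis: accumulate tap-shifted contiguous x-runs so reads and
    // writes stream through memory instead of striding per line
    int na = axis == 1 ? ny : nz;
    long st = axis == 1 ? sy : sz;
    int nc = axis == 1 ? nz : ny;
    long sc = axis == 1 ? sz : sy;
    for (int c = 0; c < nc; ++c) {
      long cbase = c * sc;
      for (int i = 0; i < na; ++i) {
        double* dst = &tmp[cbase + i * st];
        std::fill(dst, dst + nx, 0.0);
        for (int q = -r; q <= r; ++q) {
          int j = i + q;
          if (j < 0 || j >= na) j = reflect(j, na);
          const double* src = &v[cbase + (long)j * st];
          double w = k[q + r];
          for (int b = 0; b < nx; ++b) dst[b] += w * src[b];
        }
      }
    }
  }
  v.swap(tmp);
}

// [[Rcpp::export(name = ".gauss_smooth3")]]
NumericVector gauss_smooth3(NumericVector vol, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  std::vector<double> v(vol.begin(), vol.end()), tmp(n);
  std::vector<double> k = gauss_kernel(sigma);
  for (int ax = 0; ax < 3; ++ax) smooth_axis(v, tmp, nx, ny, nz, ax, k);
  NumericVector out(n);
  std::copy(v.begin(), v.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// eigenvalues of a symmetric 3x3, descending (trigonometric method)
static inline void eig_sym3(double a11, double a22, double a33,
                            double a12, double a13, double a23,
                            double* e) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-300) {
    e[0] = a11; e[1] = a22; e[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13)
                + b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    e[0] = q + 2.0 * p * std::cos(phi);
    e[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    e[1] = 3.0 * q - e[0] - e[2];
  }
  // sort descending
  if (e[0] < e[1]) std::swap(e[0], e[1]);
  if (e[1] < e[2]) std::swap(e[1], e[2]);
  if (e[0] < e[1]) std::swap(e[0], e[1]);
}

// Hessian (central differences) of the *smoothed* volume, negated so bright
// blobs give positive curvatures. what = 0: return ks only; 1: k1,k2,k3.
// [[Rcpp::export(name = ".hessian_curvatures")]]
List hessian_curvatures(NumericVector smoothed, IntegerVector dim, int what) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  const double* v = smoothed.begin();
  long sx = 1, sy = nx, sz = (long)nx * ny;
  NumericVector ks(what == 0 ? n : 0);
  NumericVector k1(what == 1 ? n : 0), k2(what == 1 ? n : 0), k3(what == 1 ? n : 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        long i = x * sx + y * sy + z * sz;
        double e[3];
        if (x < 1 || x >= nx - 1 || y < 1 || y >= ny - 1 || z < 1 || z >= nz - 1) {
          e[0] = e[1] = e[2] = 0.0;
        } else {
          double c = v[i];
          double hxx = v[i - sx] - 2 * c + v[i + sx];
          double hyy = v[i - sy] - 2 * c + v[i + sy];
          double hzz = v[i - sz] - 2 * c + v[i + sz];
          // the smallest eigenvalue is bounded above by the smallest
          // diagonal entry: a non-positive diagonal already forces a
          // zero blob score, no eigendecomposition needed
          if (what == 0 && (hxx >= 0 || hyy >= 0 || hzz >= 0)) {
            ks[i] = 0.0;
            continue;
          }
          double hxy = (v[i + sx + sy] - v[i + sx - sy] - v[i - sx + sy] + v[i - sx - sy]) / 4.0;
          double hxz = (v[i + sx + sz] - v[i + sx - sz] - v[i - sx + sz] + v[i - sx - sz]) / 4.0;
          double hyz = (v[i + sy + sz] - v[i + sy - sz] - v[i - sy + sz] + v[i - sy - sz]) / 4.0;
          eig_sym3(-hxx, -hyy, -hzz, -hxy, -hxz, -hyz, e);
        }
        if (what == 0) {
          double a = e[0] > 0 ? e[0] : 0, b = e[1] > 0 ? e[1] : 0,
                 d = e[2] > 0 ? e[2] : 0;
          ks[i] = std::cbrt(a * b * d);
        } else {
          k1[i] = e[0]; k2[i] = e[1]; k3[i] = e[2];
        }
      }
  if (what == 0) {
    ks.attr("dim") = dim;
    return List::create(_["ks"] = ks);
  }
  k1.attr("dim") = dim; k2.attr("dim") = dim; k3.attr("dim") = dim;
  return List::create(_["k1"] = k1, _["k2"] = k2, _["k3"] = k3);
}

// 26-connected components of mask; returns per-component voxel counts and
// centroids (1-based voxel coordinates, plain voxel mean)
// [[Rcpp::export(name = ".label_centroids")]]
List label_centroids(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  std::vector<int> lab(n, 0);
  const int* m = LOGICAL(mask);
  std::vector<long> stack;
  std::vector<double> cx, cy, cz;
  std::vector<int> size;
  int ncomp = 0;
  for (long seed = 0; seed < n; ++seed) {
    if (!m[seed] || m[seed] == NA_LOGICAL || lab[seed]) continue;
    ++ncomp;
    double sx = 0, sy = 0, sz = 0;
    int cnt = 0;
    stack.clear();
    stack.push_back(seed);
    lab[seed] = ncomp;
    while (!stack.empty()) {
      long cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny), z = (int)(cur / ((long)nx * ny));
      sx += x + 1; sy += y + 1; sz += z + 1; ++cnt;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
            long q = X + (long)nx * Y + (long)nx * ny * Z;
            if (m[q] && m[q] != NA_LOGICAL && !lab[q]) {
              lab[q] = ncomp;
              stack.push_back(q);
            }
          }
    }
    cx.push_back(sx / cnt); cy.push_back(sy / cnt); cz.push_back(sz / cnt);
    size.push_back(cnt);
  }
  NumericMatrix cen(ncomp, 3);
  IntegerVector sz_(ncomp);
  for (int i = 0; i < ncomp; ++i) {
    cen(i, 0) = cx[i]; cen(i, 1) = cy[i]; cen(i, 2) = cz[i];
    sz_[i] = size[i];
  }
  return List::create(_["centroids"] = cen, _["sizes"] = sz_);
}

// in-place blob renderer: mutates `vol` (callers must own it exclusively)
// [[Rcpp::export(name = ".add_blobs_inplace")]]
NumericVector add_blobs_inplace(NumericVector vol, IntegerVector dim,
                                NumericMatrix centers, double sigma, double peak) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = vol;
  double* v = out.begin();
  int r = (int)std::ceil(4.0 * sigma);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int b = 0; b < centers.nrow(); ++b) {
    double px = centers(b, 0) - 1, py = centers(b, 1) - 1, pz = centers(b, 2) - 1;
    int x0 = std::max(0, (int)std::floor(px) - r), x1 = std::min(nx - 1, (int)std::ceil(px) + r);
    int y0 = std::max(0, (int)std::floor(py) - r), y1 = std::min(ny - 1, (int)std::ceil(py) + r);
    int z0 = std::max(0, (int)std::floor(pz) - r), z1 = std::min(nz - 1, (int)std::ceil(pz) + r);
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y) {
        long base = (long)nx * y + (long)nx * ny * z;
        double dy2 = (y - py) * (y - py), dz2 = (z - pz) * (z - pz);
        for (int x = x0; x <= x1; ++x) {
          double d2 = (x - px) * (x - px) + dy2 + dz2;
          v[base + x] += peak * std::exp(-d2 * inv2s2);
        }
      }
  }
  out.attr("dim") = dim;
  return out;
}

// copying variant of the blob renderer
// [[Rcpp::export(name = ".add_blobs")]]
NumericVector add_blobs(NumericVector vol, IntegerVector dim,
                        NumericMatrix centers, double sigma, double peak) {
  NumericVector out = clone(vol);
  return add_blobs_inplace(out, dim, centers, sigma, peak);
}

// count points inside an axis-aligned box intersected with a z-slab layer
// (used by the clipped-box density estimator; trivial but hot)
// [[Rcpp::export(name = ".count_in_boxes")]]
IntegerVector count_in_boxes(NumericMatrix pts, NumericMatrix lo, NumericMatrix hi) {
  int np = pts.nrow(), nb = lo.nrow();
  IntegerVector out(nb);
  for (int b = 0; b < nb; ++b) {
    int c = 0;
    for (int i = 0; i < np; ++i) {
      if (pts(i,0) >= lo(b,0) && pts(i,0) < hi(b,0) &&
          pts(i,1) >= lo(b,1) && pts(i,1) < hi(b,1) &&
          pts(i,2) >= lo(b,2) && pts(i,2) < hi(b,2)) ++c;
    }
    out[b] = c;
  }
  return out;
}

// clipped-box volumes by 3D summed-area table over the layer indicator;
// boxes given by voxel-index bounds [x0,x1] etc. (1-based, inclusive)
// [[Rcpp::export(name = ".box_label_volumes")]]
NumericVector box_label_volumes(IntegerVector labels, IntegerVector dim,
                                int layer, IntegerMatrix lo, IntegerMatrix hi) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  long n = (long)nx * ny * nz;
  std::vector<double> S(n);
  const int* L = labels.begin();
  long sx = 1, sy = nx, sz = (long)nx * ny;
  for (long i = 0; i < n; ++i) S[i] = L[i] == layer ? 1.0 : 0.0;
  // cumulative sums along x, then y, then z (streaming passes)
  for (long l = 0; l < (long)ny * nz; ++l) {
    double* p = &S[l * nx];
    for (int i = 1; i < nx; ++i) p[i] += p[i - 1];
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 1; y < ny; ++y) {
      double* cur = &S[z * sz + y * sy];
      double* prv = &S[z * sz + (y - 1) * sy];
      for (int x = 0; x < nx; ++x) cur[x] += prv[x];
    }
  for (int z = 1; z < nz; ++z) {
    double* cur = &S[z * sz];
    double* prv = &S[(z - 1) * sz];
    for (long i = 0; i < sz; ++i) cur[i] += prv[i];
  }
  // inclusive prefix query helper (0 outside)
  int nb = lo.nrow();
  NumericVector out(nb);
  #define SAT(X, Y, Z) (((X) < 0 || (Y) < 0 || (Z) < 0) ? 0.0 : S[(X) + sy * (Y) + sz * (Z)])
  for (int b = 0; b < nb; ++b) {
    int x0 = lo(b, 0) - 1, y0 = lo(b, 1) - 1, z0 = lo(b, 2) - 1;
    int x1 = hi(b, 0) - 1, y1 = hi(b, 1) - 1, z1 = hi(b, 2) - 1;
    if (x1 >= nx) x1 = nx - 1;
    if (y1 >= ny) y1 = ny - 1;
    if (z1 >= nz) z1 = nz - 1;
    out[b] = SAT(x1, y1, z1)
           - SAT(x0 - 1, y1, z1) - SAT(x1, y0 - 1, z1) - SAT(x1, y1, z0 - 1)
           + SAT(x0 - 1, y0 - 1, z1) + SAT(x0 - 1, y1, z0 - 1) + SAT(x1, y0 - 1, z0 - 1)
           - SAT(x0 - 1, y0 - 1, z0 - 1);
  }
  #undef SAT
  return out;
}
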