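// Geometry utilities: point-to-surface distances, raster thinning for
// skeleton extraction, and a surface self-intersection check.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// closest squared distance from p to triangle (a,b,c); Ericson-style
static double pt_tri2(const double* p, const double* a, const double* b,
                      const double* c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double w0, w1, w2;
  if (d1 <= 0 && d2 <= 0) { w0=1; w1=0; w2=0; }
  else {
    double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { w0=0; w1=1; w2=0; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) { double v=d1/(d1-d3); w0=1-v; w1=v; w2=0; }
      else {
        double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
        double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
        double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
        if (d6 >= 0 && d5 <= d6) { w0=0; w1=0; w2=1; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) { double v=d2/(d2-d6); w0=1-v; w1=0; w2=v; }
          else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4-d3) >= 0 && (d5-d6) >= 0) {
              double v=(d4-d3)/((d4-d3)+(d5-d6)); w0=0; w1=1-v; w2=v;
            } else {
              double dn = 1.0/(va+vb+vc);
              w1 = vb*dn; w2 = vc*dn; w0 = 1.0-w1-w2;
            }
          }
        }
      }
    }
  }
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    double q = w0*a[i] + w1*b[i] + w2*c[i] - p[i];
    s += q*q;
  }
  return s;
}

// [[Rcpp::export(name = ".point_surface_dist")]]
NumericVector point_surface_dist(NumericMatrix pts, NumericMatrix verts,
                                 IntegerMatrix tris) {
  int np = pts.nrow(), nt = tris.nrow();
  NumericVector out(np);
  std::vector<double> V(3 * verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3*i+j] = verts(i, j);
  // triangle centroids + bounding radii for pruning
  std::vector<double> cen(3 * nt), rad(nt);
  for (int t = 0; t < nt; ++t) {
    const double* a = &V[3*(tris(t,0)-1)];
    const double* b = &V[3*(tris(t,1)-1)];
    const double* c = &V[3*(tris(t,2)-1)];
    double r2 = 0;
    for (int j = 0; j < 3; ++j) cen[3*t+j] = (a[j]+b[j]+c[j])/3.0;
    const double* vs[3] = {a, b, c};
    for (int v = 0; v < 3; ++v) {
      double d2 = 0;
      for (int j = 0; j < 3; ++j) { double d = vs[v][j]-cen[3*t+j]; d2 += d*d; }
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
  }
  for (int i = 0; i < np; ++i) {
    double p[3] = { pts(i,0), pts(i,1), pts(i,2) };
    double best = 1e300;
    for (int t = 0; t < nt; ++t) {
      double dc = 0;
      for (int j = 0; j < 3; ++j) { double d = p[j]-cen[3*t+j]; dc += d*d; }
      double lb = std::sqrt(dc) - rad[t];
      if (lb > 0 && lb*lb >= best) continue;
      double d2 = pt_tri2(p, &V[3*(tris(t,0)-1)], &V[3*(tris(t,1)-1)],
                          &V[3*(tris(t,2)-1)]);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- Guo-Hall thinning (two sub-iteration) on a binary image -------------
// img is nx x ny, column-major logicals
// [[Rcpp::export(name = ".thin_raster")]]
LogicalMatrix thin_raster(LogicalMatrix img) {
  int nx = img.nrow(), ny = img.ncol();
  std::vector<char> A(nx * ny, 0), mark(nx * ny, 0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      A[i + nx * j] = img(i, j) ? 1 : 0;
  #define PIX(i, j) (((i) >= 0 && (i) < nx && (j) >= 0 && (j) < ny) ? A[(i) + nx * (j)] : 0)
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      std::fill(mark.begin(), mark.end(), 0);
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          if (!A[i + nx * j]) continue;
          // neighbours p2..p9 clockwise from north
          int p2 = PIX(i, j-1), p3 = PIX(i+1, j-1), p4 = PIX(i+1, j);
          int p5 = PIX(i+1, j+1), p6 = PIX(i, j+1), p7 = PIX(i-1, j+1);
          int p8 = PIX(i-1, j),  p9 = PIX(i-1, j-1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = iter == 0 ? ((p6 | p7 | (!p9)) & p8) : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0) mark[i + nx * j] = 1;
        }
      for (int k = 0; k < nx * ny; ++k)
        if (mark[k]) { A[k] = 0; changed = true; }
    }
  }
  #undef PIX
  LogicalMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) out(i, j) = A[i + nx * j] != 0;
  return out;
}

// ---- triangle-triangle intersection test (for self-intersection checks) --

static inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1]*b[2]-a[2]*b[1]; c[1] = a[2]*b[0]-a[0]*b[2]; c[2] = a[0]*b[1]-a[1]*b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0]+a[1]*b[1]+a[2]*b[2];
}

// segment-triangle intersection helper: does segment p-q cross triangle abc?
static bool seg_tri(const double* p, const double* q, const double* a,
                    const double* b, const double* c) {
  double ab[3], ac[3], qp[3], n[3], ap[3];
  for (int i=0;i<3;++i){ ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; qp[i]=p[i]-q[i]; ap[i]=p[i]-a[i]; }
  cross3(ab, ac, n);
  double d = dot3(qp, n);
  if (std::fabs(d) < 1e-300) return false;
  double t = dot3(ap, n) / d;
  if (t < 0 || t > 1) return false;
  double e[3]; cross3(qp, ap, e);
  double v = dot3(ac, e) / d;
  if (v < 0 || v > 1) return false;
  double w = -dot3(ab, e) / d;
  if (w < 0 || v + w > 1) return false;
  return true;
}

// true if triangles T1=(a1,b1,c1) and T2 intersect (edge-through-face test,
// shared vertices allowed and skipped by the caller)
static bool tri_tri(const double* a1, const double* b1, const double* c1,
                    const double* a2, const double* b2, const double* c2) {
  return seg_tri(a1, b1, a2, b2, c2) || seg_tri(b1, c1, a2, b2, c2) ||
         seg_tri(c1, a1, a2, b2, c2) || seg_tri(a2, b2, a1, b1, c1) ||
         seg_tri(b2, c2, a1, b1, c1) || seg_tri(c2, a2, a1, b1, c1);
}

// count intersecting non-adjacent triangle pairs of one surface
// [[Rcpp::export(name = ".self_intersections")]]
int self_intersections(NumericMatrix verts, IntegerMatrix tris) {
  int nt = tris.nrow();
  std::vector<double> V(3 * verts.nrow());
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3*i+j] = verts(i, j);
  // bounding boxes
  std::vector<double> lo(3*nt), hi(3*nt);
  for (int t = 0; t < nt; ++t) {
    for (int j = 0; j < 3; ++j) { lo[3*t+j] = 1e300; hi[3*t+j] = -1e300; }
    for (int v = 0; v < 3; ++v) {
      const double* p = &V[3*(tris(t,v)-1)];
      for (int j = 0; j < 3; ++j) {
        if (p[j] < lo[3*t+j]) lo[3*t+j] = p[j];
        if (p[j] > hi[3*t+j]) hi[3*t+j] = p[j];
      }
    }
  }
  int count = 0;
  for (int s = 0; s < nt; ++s) {
    for (int t = s + 1; t < nt; ++t) {
      bool sep = false;
      for (int j = 0; j < 3; ++j)
        if (lo[3*s+j] > hi[3*t+j] || lo[3*t+j] > hi[3*s+j]) { sep = true; break; }
      if (sep) continue;
      bool shared = false;
      for (int u = 0; u < 3 && !shared; ++u)
        for (int w = 0; w < 3; ++w)
          if (tris(s, u) == tris(t, w)) { shared = true; break; }
      if (shared) continue;
      if (tri_tri(&V[3*(tris(s,0)-1)], &V[3*(tris(s,1)-1)], &V[3*(tris(s,2)-1)],
                  &V[3*(tris(t,0)-1)], &V[3*(tris(t,1)-1)], &V[3*(tris(t,2)-1)]))
        ++count;
    }
  }
  return count;
}
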