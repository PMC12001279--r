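// Morphoelastic neo-Hookean FEM on linear tetrahedra (single quadrature
// point), relaxed to steady state with damped explicit dynamics, penalty
// contact and a saturating growth ramp. Lumped unit nodal masses: the mass
// is fictitious at steady state, so it is chosen for time-step economy.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

typedef double real;

struct Mat3 {
  real a[9]; // row-major
  inline real& operator()(int i, int j) { return a[3 * i + j]; }
  inline real operator()(int i, int j) const { return a[3 * i + j]; }
};

static inline Mat3 matmul(const Mat3& A, const Mat3& B) {
  Mat3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C(i, j) = A(i, 0) * B(0, j) + A(i, 1) * B(1, j) + A(i, 2) * B(2, j);
  return C;
}

static inline real det3(const Mat3& M) {
  return M(0,0) * (M(1,1) * M(2,2) - M(1,2) * M(2,1))
       - M(0,1) * (M(1,0) * M(2,2) - M(1,2) * M(2,0))
       + M(0,2) * (M(1,0) * M(2,1) - M(1,1) * M(2,0));
}

static inline Mat3 inv3(const Mat3& M, real d) {
  Mat3 I;
  real id = 1.0 / d;
  I(0,0) =  (M(1,1) * M(2,2) - M(1,2) * M(2,1)) * id;
  I(0,1) = -(M(0,1) * M(2,2) - M(0,2) * M(2,1)) * id;
  I(0,2) =  (M(0,1) * M(1,2) - M(0,2) * M(1,1)) * id;
  I(1,0) = -(M(1,0) * M(2,2) - M(1,2) * M(2,0)) * id;
  I(1,1) =  (M(0,0) * M(2,2) - M(0,2) * M(2,0)) * id;
  I(1,2) = -(M(0,0) * M(1,2) - M(0,2) * M(1,0)) * id;
  I(2,0) =  (M(1,0) * M(2,1) - M(1,1) * M(2,0)) * id;
  I(2,1) = -(M(0,0) * M(2,1) - M(0,1) * M(2,0)) * id;
  I(2,2) =  (M(0,0) * M(1,1) - M(0,1) * M(1,0)) * id;
  return I;
}

struct ElemRef {
  int n[4];
  real g[4][3];   // reference shape-function gradients
  real V0;
  real mu, K;
  real lamN, lamT;
  real N[3];
};

// growth tensor inverse and Jg in closed form (rank-one update structure)
static inline void growth_inv(const ElemRef& e, real s, Mat3& Fginv, real& Jg) {
  real aN = 1.0 + e.lamN * s, aT = 1.0 + e.lamT * s;
  Jg = aN * aT * aT;
  real cN = 1.0 / aN - 1.0 / aT;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      Fginv(i, j) = (i == j ? 1.0 / aT : 0.0) + cN * e.N[i] * e.N[j];
}

// First Piola-Kirchhoff stress of the neo-Hookean energy wrt Fe
// P = mu J^{-2/3} (Fe - tr(b)/3 Fe^{-T}) + K (J - 1) Fe^{-T}
static inline bool piola(const Mat3& Fe, real mu, real K,
                         Mat3& P, real& J, real& psi) {
  J = det3(Fe);
  if (!(J > 1e-12)) return false;
  Mat3 FeinvT;
  {
    Mat3 Feinv = inv3(Fe, J);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) FeinvT(i, j) = Feinv(j, i);
  }
  real trb = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) trb += Fe(i, j) * Fe(i, j);
  real Jm23 = std::pow(J, -2.0 / 3.0);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      P(i, j) = mu * Jm23 * (Fe(i, j) - trb / 3.0 * FeinvT(i, j))
              + K * (J - 1.0) * FeinvT(i, j);
  psi = 0.5 * mu * (trb * Jm23 - 3.0) + K * (J - std::log(J) - 1.0);
  return true;
}

static void build_elems(const NumericMatrix& nodes, const IntegerMatrix& tets,
                        const NumericVector& mu, const NumericVector& K,
                        const NumericVector& lamN, const NumericVector& lamT,
                        const NumericMatrix& normals,
                        std::vector<ElemRef>& elems) {
  int m = tets.nrow();
  elems.resize(m);
  for (int e = 0; e < m; ++e) {
    ElemRef& E = elems[e];
    for (int a = 0; a < 4; ++a) E.n[a] = tets(e, a) - 1;
    Mat3 Dm;
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < 3; ++i)
        Dm(i, c) = nodes(E.n[c + 1], i) - nodes(E.n[0], i);
    real d = det3(Dm);
    if (!(d > 0)) stop("element %d has non-positive reference volume", e + 1);
    E.V0 = d / 6.0;
    Mat3 Bm = inv3(Dm, d);
    // F = Ds * Bm; grad of node a+1 (a=1..3) is row a of Bm; node 0 = -sum
    for (int j = 0; j < 3; ++j) {
      E.g[1][j] = Bm(0, j); E.g[2][j] = Bm(1, j); E.g[3][j] = Bm(2, j);
      E.g[0][j] = -(Bm(0, j) + Bm(1, j) + Bm(2, j));
    }
    E.mu = mu[e]; E.K = K[e]; E.lamN = lamN[e]; E.lamT = lamT[e];
    for (int i = 0; i < 3; ++i) E.N[i] = normals(e, i);
  }
}

// internal forces at positions x for growth saturation s; returns false on
// element inversion (bad element index written to *bad)
static bool internal_forces(const std::vector<ElemRef>& elems,
                            const std::vector<real>& x, int n,
                            real s, std::vector<real>& f,
                            real* energy, int* bad) {
  std::fill(f.begin(), f.end(), 0.0);
  real etot = 0.0;
  for (size_t e = 0; e < elems.size(); ++e) {
    const ElemRef& E = elems[e];
    Mat3 F;
    const real* x0 = &x[3 * E.n[0]];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        real acc = 0.0;
        for (int a = 1; a < 4; ++a)
          acc += (x[3 * E.n[a] + i] - x0[i]) * E.g[a][j];
        F(i, j) = acc;
      }
    Mat3 Fginv; real Jg;
    growth_inv(E, s, Fginv, Jg);
    Mat3 Fe = matmul(F, Fginv);
    Mat3 P; real J, psi;
    if (!piola(Fe, E.mu, E.K, P, J, psi)) { if (bad) *bad = (int)e + 1; return false; }
    etot += E.V0 * Jg * psi;
    // Ptot = P * Fginv^T (Fginv symmetric here, but keep the transpose)
    Mat3 Pt;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Pt(i, j) = P(i,0) * Fginv(j,0) + P(i,1) * Fginv(j,1) + P(i,2) * Fginv(j,2);
    real w = E.V0 * Jg;
    for (int a = 0; a < 4; ++a) {
      real* fa = &f[3 * E.n[a]];
      for (int i = 0; i < 3; ++i)
        fa[i] -= w * (Pt(i,0) * E.g[a][0] + Pt(i,1) * E.g[a][1] + Pt(i,2) * E.g[a][2]);
    }
  }
  if (energy) *energy = etot;
  return true;
}

// ---------------- contact -----------------------------------------------

struct ContactPairs {
  // candidate node-triangle pairs, refreshed periodically
  std::vector<int> node;
  std::vector<int> tri;
};

struct CellKey {
  int64_t k;
  bool operator==(const CellKey& o) const { return k == o.k; }
};
struct CellHash { size_t operator()(const CellKey& c) const { return std::hash<int64_t>()(c.k); } };

static inline int64_t cellkey(int ix, int iy, int iz) {
  return ((int64_t)(ix + (1 << 20)) << 42) ^ ((int64_t)(iy + (1 << 20)) << 21) ^ (int64_t)(iz + (1 << 20));
}

static void find_pairs(const std::vector<real>& x,
                       const IntegerMatrix& tris,
                       const std::vector<int>& snodes,
                       const std::vector<std::vector<int> >& excl,
                       real range, ContactPairs& cp) {
  cp.node.clear(); cp.tri.clear();
  int nt = tris.nrow();
  if (nt == 0 || snodes.empty()) return;
  real cell = 2.0 * range;
  std::unordered_map<int64_t, std::vector<int> > grid;
  for (int t = 0; t < nt; ++t) {
    real lo[3], hi[3];
    for (int i = 0; i < 3; ++i) { lo[i] = 1e300; hi[i] = -1e300; }
    for (int v = 0; v < 3; ++v) {
      const real* p = &x[3 * (tris(t, v) - 1)];
      for (int i = 0; i < 3; ++i) {
        if (p[i] < lo[i]) lo[i] = p[i];
        if (p[i] > hi[i]) hi[i] = p[i];
      }
    }
    int lox = (int)std::floor((lo[0] - range) / cell), hix = (int)std::floor((hi[0] + range) / cell);
    int loy = (int)std::floor((lo[1] - range) / cell), hiy = (int)std::floor((hi[1] + range) / cell);
    int loz = (int)std::floor((lo[2] - range) / cell), hiz = (int)std::floor((hi[2] + range) / cell);
    for (int ix = lox; ix <= hix; ++ix)
      for (int iy = loy; iy <= hiy; ++iy)
        for (int iz = loz; iz <= hiz; ++iz)
          grid[cellkey(ix, iy, iz)].push_back(t);
  }
  for (size_t si = 0; si < snodes.size(); ++si) {
    int nd = snodes[si];
    const real* p = &x[3 * nd];
    int ix = (int)std::floor(p[0] / cell);
    int iy = (int)std::floor(p[1] / cell);
    int iz = (int)std::floor(p[2] / cell);
    std::unordered_map<int64_t, std::vector<int> >::iterator it = grid.find(cellkey(ix, iy, iz));
    if (it == grid.end()) continue;
    const std::vector<int>& cand = it->second;
    const std::vector<int>& ex = excl[nd];
    for (size_t c = 0; c < cand.size(); ++c) {
      int t = cand[c];
      bool skip = false;
      for (size_t q = 0; q < ex.size(); ++q) if (ex[q] == t) { skip = true; break; }
      if (skip) continue;
      // coarse distance prefilter: node vs triangle centroid
      double cx = 0, cy = 0, cz = 0, rr = 0;
      for (int v = 0; v < 3; ++v) {
        const double* tv = &x[3 * (tris(t, v) - 1)];
        cx += tv[0]; cy += tv[1]; cz += tv[2];
      }
      cx /= 3; cy /= 3; cz /= 3;
      for (int v = 0; v < 3; ++v) {
        const double* tv = &x[3 * (tris(t, v) - 1)];
        double dd = (tv[0]-cx)*(tv[0]-cx) + (tv[1]-cy)*(tv[1]-cy) + (tv[2]-cz)*(tv[2]-cz);
        if (dd > rr) rr = dd;
      }
      double dx = p[0]-cx, dy = p[1]-cy, dz = p[2]-cz;
      double margin = 2.0 * range + std::sqrt(rr);
      if (dx*dx + dy*dy + dz*dz > margin * margin) continue;
      cp.node.push_back(nd); cp.tri.push_back(t);
    }
  }
}

// closest point on triangle (p0,p1,p2) to p; returns squared distance and
// barycentric weights
static real point_tri(const real* p, const real* a, const real* b,
                      const real* c, real* w) {
  real ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  real d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  real d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { w[0]=1; w[1]=0; w[2]=0; }
  else {
    real bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
    real d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    real d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { w[0]=0; w[1]=1; w[2]=0; }
    else {
      real vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        real v = d1 / (d1 - d3); w[0]=1-v; w[1]=v; w[2]=0;
      } else {
        real cp2[3]; for (int i=0;i<3;++i) cp2[i]=p[i]-c[i];
        real d5 = ab[0]*cp2[0]+ab[1]*cp2[1]+ab[2]*cp2[2];
        real d6 = ac[0]*cp2[0]+ac[1]*cp2[1]+ac[2]*cp2[2];
        if (d6 >= 0 && d5 <= d6) { w[0]=0; w[1]=0; w[2]=1; }
        else {
          real vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            real v2 = d2 / (d2 - d6); w[0]=1-v2; w[1]=0; w[2]=v2;
          } else {
            real va = d3*d6 - d5*d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              real v3 = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              w[0]=0; w[1]=1-v3; w[2]=v3;
            } else {
              real denom = 1.0 / (va + vb + vc);
              w[1] = vb * denom; w[2] = vc * denom; w[0] = 1.0 - w[1] - w[2];
            }
          }
        }
      }
    }
  }
  real q[3], d2sum = 0.0;
  for (int i = 0; i < 3; ++i) {
    q[i] = w[0]*a[i] + w[1]*b[i] + w[2]*c[i] - p[i];
    d2sum += q[i]*q[i];
  }
  return d2sum;
}

static void contact_forces_impl(const std::vector<real>& x,
                                const IntegerMatrix& tris,
                                const ContactPairs& cp,
                                real range, real kc,
                                std::vector<real>& f) {
  for (size_t q = 0; q < cp.node.size(); ++q) {
    int nd = cp.node[q], t = cp.tri[q];
    const real* p = &x[3 * nd];
    int i0 = tris(t,0)-1, i1 = tris(t,1)-1, i2 = tris(t,2)-1;
    real w[3];
    real d2 = point_tri(p, &x[3*i0], &x[3*i1], &x[3*i2], w);
    if (d2 >= range * range || d2 < 1e-24) continue;
    real d = std::sqrt(d2);
    real qpt[3], dir[3];
    for (int i = 0; i < 3; ++i) {
      qpt[i] = w[0]*x[3*i0+i] + w[1]*x[3*i1+i] + w[2]*x[3*i2+i];
      dir[i] = (p[i] - qpt[i]) / d;
    }
    real mag = kc * (range - d);
    for (int i = 0; i < 3; ++i) {
      real fi = mag * dir[i];
      f[3*nd+i]   += fi;
      f[3*i0+i]   -= w[0] * fi;
      f[3*i1+i]   -= w[1] * fi;
      f[3*i2+i]   -= w[2] * fi;
    }
  }
}

// 1-ring (by surface triangles) exclusion sets: node -> triangles sharing a
// vertex with any triangle containing the node
static void build_exclusions(const IntegerMatrix& tris, int n,
                             std::vector<int>& snodes,
                             std::vector<std::vector<int> >& excl) {
  int nt = tris.nrow();
  std::vector<std::vector<int> > vtx2tri(n);
  std::vector<char> issurf(n, 0);
  for (int t = 0; t < nt; ++t)
    for (int v = 0; v < 3; ++v) {
      int nd = tris(t, v) - 1;
      vtx2tri[nd].push_back(t);
      issurf[nd] = 1;
    }
  snodes.clear();
  for (int i = 0; i < n; ++i) if (issurf[i]) snodes.push_back(i);
  excl.assign(n, std::vector<int>());
  for (size_t si = 0; si < snodes.size(); ++si) {
    int nd = snodes[si];
    std::vector<int>& ex = excl[nd];
    for (size_t a = 0; a < vtx2tri[nd].size(); ++a) {
      int t = vtx2tri[nd][a];
      for (int v = 0; v < 3; ++v) {
        int ov = tris(t, v) - 1;
        for (size_t b = 0; b < vtx2tri[ov].size(); ++b) ex.push_back(vtx2tri[ov][b]);
      }
    }
    std::sort(ex.begin(), ex.end());
    ex.erase(std::unique(ex.begin(), ex.end()), ex.end());
  }
}

// ---------------- exported entry points ----------------------------------

// [[Rcpp::export(name = ".fem_forces")]]
List fem_forces(NumericMatrix nodes, IntegerMatrix tets,
                NumericVector mu, NumericVector K,
                NumericVector lamN, NumericVector lamT,
                NumericMatrix normals, NumericMatrix x, double s) {
  std::vector<ElemRef> elems;
  build_elems(nodes, tets, mu, K, lamN, lamT, normals, elems);
  int n = nodes.nrow();
  std::vector<real> xv(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) xv[3 * i + j] = x(i, j);
  real energy = 0.0; int bad = 0;
  if (!internal_forces(elems, xv, n, s, f, &energy, &bad))
    stop("inverted element (det Fe <= 0) at element %d", bad);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = f[3 * i + j];
  return List::create(_["forces"] = out, _["energy"] = energy);
}

// [[Rcpp::export(name = ".fem_contact")]]
NumericMatrix fem_contact(NumericMatrix x, IntegerMatrix tris,
                          double range, double stiffness) {
  int n = x.nrow();
  std::vector<real> xv(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) xv[3 * i + j] = x(i, j);
  std::vector<int> snodes;
  std::vector<std::vector<int> > excl;
  build_exclusions(tris, n, snodes, excl);
  ContactPairs cp;
  find_pairs(xv, tris, snodes, excl, range, cp);
  contact_forces_impl(xv, tris, cp, range, stiffness, f);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = f[3 * i + j];
  return out;
}

// [[Rcpp::export(name = ".fem_relax")]]
List fem_relax(NumericMatrix nodes, IntegerMatrix tets,
               NumericVector mu, NumericVector K,
               NumericVector lamN, NumericVector lamT,
               NumericMatrix normals, IntegerVector fixed,
               NumericMatrix x0, IntegerMatrix stris,
               List config) {
  int n = nodes.nrow();
  std::vector<ElemRef> elems;
  build_elems(nodes, tets, mu, K, lamN, lamT, normals, elems);

  double beta       = as<double>(config["beta"]);
  double dt         = as<double>(config["time_step"]);
  double damp       = as<double>(config["damping_coefficient"]);
  double kc         = as<double>(config["contact_stiffness"]);
  double range      = as<double>(config["contact_range"]);
  double ftol       = as<double>(config["force_tolerance"]);
  int    max_steps  = as<int>(config["max_steps"]);
  double ramp_end   = as<double>(config["growth_ramp_end"]);
  int    log_every  = as<int>(config["log_every"]);
  int    pair_every = as<int>(config["contact_every"]);
  bool   use_contact = kc > 0 && range > 0 && stris.nrow() > 0;

  if (dt <= 0) {
    // stability estimate: nodal stiffness ~ sum_e (mu + K) V0 |g|^2, grown
    std::vector<real> kn(n, 0.0);
    for (size_t e = 0; e < elems.size(); ++e) {
      const ElemRef& E = elems[e];
      real grow = (1.0 + E.lamT) * (1.0 + E.lamT) * (1.0 + E.lamN);
      for (int a = 0; a < 4; ++a) {
        real g2 = E.g[a][0]*E.g[a][0] + E.g[a][1]*E.g[a][1] + E.g[a][2]*E.g[a][2];
        kn[E.n[a]] += (E.mu + E.K) * E.V0 * g2 * grow * 4.0;
      }
    }
    real kmax = 0.0;
    for (int i = 0; i < n; ++i) if (kn[i] > kmax) kmax = kn[i];
    if (use_contact && kc > kmax) kmax = kc;
    dt = 0.5 * 2.0 / std::sqrt(kmax > 0 ? kmax : 1.0);
  }

  std::vector<char> isfix(n, 0);
  for (int i = 0; i < fixed.size(); ++i) isfix[fixed[i] - 1] = 1;

  std::vector<real> x(3 * n), v(3 * n, 0.0), f(3 * n), fc(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) x[3 * i + j] = x0(i, j);

  std::vector<int> snodes;
  std::vector<std::vector<int> > excl;
  ContactPairs cp;
  if (use_contact) build_exclusions(stris, n, snodes, excl);

  std::vector<double> log_t, log_res, log_en;
  double t = 0.0;
  bool converged = false;
  int step = 0, bad = 0;
  double residual = NA_REAL, energy = NA_REAL;

  for (step = 1; step <= max_steps; ++step) {
    t += dt;
    double s = 1.0 - std::exp(-beta * t);
    if (!internal_forces(elems, x, n, s, f, &energy, &bad))
      stop("inverted element (det Fe <= 0) at element %d, step %d", bad, step);
    if (use_contact) {
      if ((step - 1) % pair_every == 0)
        find_pairs(x, stris, snodes, excl, range, cp);
      std::fill(fc.begin(), fc.end(), 0.0);
      contact_forces_impl(x, stris, cp, range, kc, fc);
      for (int i = 0; i < 3 * n; ++i) f[i] += fc[i];
    }
    real rmax2 = 0.0;
    real vd = 1.0 - damp * dt;
    if (vd < 0.0) vd = 0.0;
    for (int i = 0; i < n; ++i) {
      if (isfix[i]) { v[3*i]=v[3*i+1]=v[3*i+2]=0.0; continue; }
      real fx = f[3*i], fy = f[3*i+1], fz = f[3*i+2];
      real r2 = fx*fx + fy*fy + fz*fz;
      if (r2 > rmax2) rmax2 = r2;
      v[3*i]   = vd * v[3*i]   + dt * fx;
      v[3*i+1] = vd * v[3*i+1] + dt * fy;
      v[3*i+2] = vd * v[3*i+2] + dt * fz;
      x[3*i]   += dt * v[3*i];
      x[3*i+1] += dt * v[3*i+1];
      x[3*i+2] += dt * v[3*i+2];
    }
    residual = std::sqrt(rmax2);
    if (step % log_every == 0 || step == 1) {
      log_t.push_back(t); log_res.push_back(residual); log_en.push_back(energy);
    }
    if (beta * t >= ramp_end && residual < ftol) { converged = true; break; }
  }
  if (step > max_steps) step = max_steps;

  // final per-element state
  int m = (int)elems.size();
  double s_end = 1.0 - std::exp(-beta * t);
  NumericMatrix Fout(m, 9), Fgout(m, 9), Feout(m, 9), Sout(m, 9);
  NumericVector Jout(m), Psiout(m);
  for (int e = 0; e < m; ++e) {
    const ElemRef& E = elems[e];
    Mat3 F;
    const real* xp0 = &x[3 * E.n[0]];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        real acc = 0.0;
        for (int a = 1; a < 4; ++a)
          acc += (x[3 * E.n[a] + i] - xp0[i]) * E.g[a][j];
        F(i, j) = acc;
      }
    Mat3 Fginv; real Jg;
    growth_inv(E, s_end, Fginv, Jg);
    Mat3 Fe = matmul(F, Fginv);
    Mat3 P; real J, psi;
    if (!piola(Fe, E.mu, E.K, P, J, psi))
      stop("inverted element in final state at element %d", e + 1);
    // sigma = (1/J) P Fe^T
    Mat3 sig;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        sig(i, j) = (P(i,0)*Fe(j,0) + P(i,1)*Fe(j,1) + P(i,2)*Fe(j,2)) / J;
    real aN = 1.0 + E.lamN * s_end, aT = 1.0 + E.lamT * s_end;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        int c = 3 * i + j;
        Fout(e, c) = F(i, j);
        Fgout(e, c) = (i == j ? aT : 0.0) + (aN - aT) * E.N[i] * E.N[j];
        Feout(e, c) = Fe(i, j);
        Sout(e, c) = sig(i, j);
      }
    Jout[e] = J; Psiout[e] = psi;
  }

  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      xout(i, j) = x[3 * i + j];
      vout(i, j) = v[3 * i + j];
    }
  return List::create(
    _["x"] = xout, _["v"] = vout, _["t"] = t, _["steps"] = step,
    _["dt"] = dt, _["converged"] = converged, _["residual"] = residual,
    _["F"] = Fout, _["Fg"] = Fgout, _["Fe"] = Feout, _["sigma"] = Sout,
    _["J"] = Jout, _["psi"] = Psiout,
    _["log_t"] = wrap(log_t), _["log_residual"] = wrap(log_res),
    _["log_energy"] = wrap(log_en));
}
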