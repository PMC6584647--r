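// Compute kernels: torsion-space chain building, restraint target function,
// simulated annealing, Gaussian map simulation, trilinear interpolation,
// density-gradient flexible fitting, and symmetry-replicated MC refinement.
//
// Atom layout: 6 atoms per residue in fixed slot order
//   0=N, 1=CA, 2=C, 3=O, 4=CB, 5=SC (side-chain centroid pseudo-atom)
// so atom index of slot s in residue r (0-based) is 6*r + s.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// ideal covalent geometry (trans peptide)
static const double B_NCA = 1.458, B_CAC = 1.525, B_CN = 1.329;
static const double B_CO = 1.231, B_CACB = 1.521, B_CASC = 2.40;
static const double A_NCAC = 111.0, A_CACN = 117.2, A_CNCA = 121.7, A_CACO = 120.8;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 vscale(const Vec3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }
static inline Vec3 vunit(const Vec3 &a) {
  double n = vnorm(a);
  return {a.x / n, a.y / n, a.z / n};
}

// place D given A-B-C, bond |CD|, angle B-C-D (deg), torsion A-B-C-D (deg)
static Vec3 nerf(const Vec3 &A, const Vec3 &B, const Vec3 &C,
                 double bond, double angle, double torsion) {
  double th = angle * DEG, chi = torsion * DEG;
  Vec3 ab = vsub(B, A), bc = vsub(C, B);
  Vec3 bcn = vunit(bc);
  Vec3 n = vunit(vcross(ab, bcn));
  Vec3 m = vcross(n, bcn);
  double d1 = -bond * std::cos(th);
  double d2 = bond * std::sin(th) * std::cos(chi);
  double d3 = bond * std::sin(th) * std::sin(chi);
  return {C.x + bcn.x * d1 + m.x * d2 + n.x * d3,
          C.y + bcn.y * d1 + m.y * d2 + n.y * d3,
          C.z + bcn.z * d1 + m.z * d2 + n.z * d3};
}

// signed torsion angle a-b-c-d in degrees
static double dihedral(const Vec3 &a, const Vec3 &b, const Vec3 &c, const Vec3 &d) {
  Vec3 b1 = vsub(b, a), b2 = vsub(c, b), b3 = vsub(d, c);
  Vec3 n1 = vcross(b1, b2), n2 = vcross(b2, b3);
  Vec3 b2n = vunit(b2);
  double x = vdot(n1, n2);
  double y = vdot(vcross(n1, n2), b2n);
  return std::atan2(y, x) / DEG;
}

// side-chain direction: unit vector u with angle(N-CA-u)=110.4, angle(C-CA-u)=110.6
static Vec3 cb_dir(const Vec3 &N, const Vec3 &CA, const Vec3 &C) {
  Vec3 n1 = vunit(vsub(N, CA)), n2 = vunit(vsub(C, CA));
  double c12 = vdot(n1, n2);
  double cN = std::cos(110.4 * DEG), cC = std::cos(110.6 * DEG);
  double det = 1.0 - c12 * c12;
  double a = (cN - cC * c12) / det;
  double b = (cC - cN * c12) / det;
  double c2 = 1.0 - (a * a + b * b + 2.0 * a * b * c12);
  double c = c2 > 0 ? std::sqrt(c2) : 0.0;
  Vec3 p = vunit(vcross(n1, n2));
  return vunit({a * n1.x + b * n2.x + c * p.x,
                a * n1.y + b * n2.y + c * p.y,
                a * n1.z + b * n2.z + c * p.z});
}

// build full reduced backbone from torsions; phi[0] is ignored, psi[n-1]
// only orients the terminal carbonyl oxygen.
static void build_chain(const std::vector<double> &phi, const std::vector<double> &psi,
                        std::vector<Vec3> &xyz) {
  int n = (int)phi.size();
  xyz.resize(6 * n);
  // first residue in a canonical frame
  Vec3 N0 = {0.0, 0.0, 0.0};
  Vec3 CA0 = {B_NCA, 0.0, 0.0};
  double th = A_NCAC * DEG;
  Vec3 C0 = {CA0.x - B_CAC * std::cos(th), B_CAC * std::sin(th), 0.0};
  xyz[0] = N0; xyz[1] = CA0; xyz[2] = C0;
  for (int i = 0; i < n; ++i) {
    Vec3 N = xyz[6 * i + 0], CA = xyz[6 * i + 1], C = xyz[6 * i + 2];
    // carbonyl O: torsion N-CA-C-O = psi + 180
    xyz[6 * i + 3] = nerf(N, CA, C, B_CO, A_CACO, psi[i] + 180.0);
    Vec3 u = cb_dir(N, CA, C);
    xyz[6 * i + 4] = vadd(CA, vscale(u, B_CACB));
    xyz[6 * i + 5] = vadd(CA, vscale(u, B_CASC));
    if (i + 1 < n) {
      Vec3 Nn = nerf(N, CA, C, B_CN, A_CACN, psi[i]);
      Vec3 CAn = nerf(CA, C, Nn, B_NCA, A_CNCA, 180.0);  // omega fixed trans
      Vec3 Cn = nerf(C, Nn, CAn, B_CAC, A_NCAC, phi[i + 1]);
      xyz[6 * (i + 1) + 0] = Nn;
      xyz[6 * (i + 1) + 1] = CAn;
      xyz[6 * (i + 1) + 2] = Cn;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix build_chain_cpp(NumericVector phi, NumericVector psi) {
  int n = phi.size();
  std::vector<double> p(phi.begin(), phi.end()), s(psi.begin(), psi.end());
  std::vector<Vec3> xyz;
  build_chain(p, s, xyz);
  NumericMatrix out(6 * n, 3);
  for (int i = 0; i < 6 * n; ++i) {
    out(i, 0) = xyz[i].x; out(i, 1) = xyz[i].y; out(i, 2) = xyz[i].z;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix dihedrals_from_coords_cpp(NumericMatrix coords, int nres) {
  NumericMatrix out(nres, 2);  // phi, psi
  auto at = [&](int idx) { return Vec3{coords(idx, 0), coords(idx, 1), coords(idx, 2)}; };
  for (int i = 0; i < nres; ++i) {
    if (i == 0) out(i, 0) = NA_REAL;
    else out(i, 0) = dihedral(at(6 * (i - 1) + 2), at(6 * i), at(6 * i + 1), at(6 * i + 2));
    if (i + 1 < nres)
      out(i, 1) = dihedral(at(6 * i), at(6 * i + 1), at(6 * i + 2), at(6 * (i + 1)));
    else {
      double o = dihedral(at(6 * i), at(6 * i + 1), at(6 * i + 2), at(6 * i + 3));
      double ps = o - 180.0;
      if (ps <= -180.0) ps += 360.0;
      out(i, 1) = ps;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// target function

struct Restraints {
  // distance restraints, flattened candidate lists
  std::vector<int> grp;        // offsets, length nr+1
  std::vector<int> ai, aj;     // candidate atom indices (0-based)
  std::vector<double> lower, upper;
  // dihedral restraints
  std::vector<int> dres, dtyp; // residue (0-based), 0=phi 1=psi
  std::vector<double> dtarget, dtol;
  double w_upper, w_lower, w_dih, w_steric, rmin;
  int nres;
  std::vector<int> steric_atoms;  // CA + SC atom indices
  std::vector<int> steric_res;
};

static Restraints make_restraints(int nres, IntegerVector grp, IntegerVector ai,
                                  IntegerVector aj, NumericVector lower, NumericVector upper,
                                  IntegerVector dres, IntegerVector dtyp,
                                  NumericVector dtarget, NumericVector dtol,
                                  NumericVector weights, double rmin) {
  Restraints R;
  R.nres = nres;
  R.grp.assign(grp.begin(), grp.end());
  R.ai.assign(ai.begin(), ai.end());
  R.aj.assign(aj.begin(), aj.end());
  R.lower.assign(lower.begin(), lower.end());
  R.upper.assign(upper.begin(), upper.end());
  R.dres.assign(dres.begin(), dres.end());
  R.dtyp.assign(dtyp.begin(), dtyp.end());
  R.dtarget.assign(dtarget.begin(), dtarget.end());
  R.dtol.assign(dtol.begin(), dtol.end());
  R.w_upper = weights[0]; R.w_lower = weights[1];
  R.w_dih = weights[2]; R.w_steric = weights[3];
  R.rmin = rmin;
  for (int i = 0; i < nres; ++i) {
    R.steric_atoms.push_back(6 * i + 1); R.steric_res.push_back(i);
    R.steric_atoms.push_back(6 * i + 5); R.steric_res.push_back(i);
  }
  return R;
}

static void regularize_core(std::vector<Vec3> &x, int nres, int sweeps);

static inline double adiff(double a, double b) {
  double d = a - b;
  while (d > 180.0) d -= 360.0;
  while (d < -180.0) d += 360.0;
  return d;
}

// distance + steric terms from coordinates
static double tf_spatial(const std::vector<Vec3> &xyz, const Restraints &R) {
  double tf = 0.0;
  int nr = (int)R.grp.size() - 1;
  for (int r = 0; r < nr; ++r) {
    int a = R.grp[r], b = R.grp[r + 1];
    double d;
    if (b - a == 1) {
      d = vnorm(vsub(xyz[R.ai[a]], xyz[R.aj[a]]));
    } else {
      double s = 0.0;  // r^-6 effective distance over candidates
      for (int k = a; k < b; ++k) {
        double dk = vnorm(vsub(xyz[R.ai[k]], xyz[R.aj[k]]));
        s += 1.0 / (dk * dk * dk * dk * dk * dk);
      }
      d = std::pow(s, -1.0 / 6.0);
    }
    if (d > R.upper[r]) { double v = d - R.upper[r]; tf += R.w_upper * v * v; }
    if (d < R.lower[r]) { double v = R.lower[r] - d; tf += R.w_lower * v * v; }
  }
  if (R.w_steric > 0) {
    double r2 = R.rmin * R.rmin;
    int ns = (int)R.steric_atoms.size();
    for (int p = 0; p < ns; ++p) {
      const Vec3 &xp = xyz[R.steric_atoms[p]];
      for (int q = p + 1; q < ns; ++q) {
        if (R.steric_res[q] - R.steric_res[p] < 2) continue;
        const Vec3 &xq = xyz[R.steric_atoms[q]];
        double dx = xp.x - xq.x, dy = xp.y - xq.y, dz = xp.z - xq.z;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < r2) {
          double v = R.rmin - std::sqrt(d2);
          tf += R.w_steric * v * v;
        }
      }
    }
  }
  return tf;
}

static double tf_dihedral(const std::vector<double> &phi, const std::vector<double> &psi,
                          const Restraints &R) {
  double tf = 0.0;
  for (size_t k = 0; k < R.dres.size(); ++k) {
    int i = R.dres[k];
    if (R.dtyp[k] == 0 && i == 0) continue;  // phi of first residue undefined
    double ang = (R.dtyp[k] == 0) ? phi[i] : psi[i];
    double v = std::fabs(adiff(ang, R.dtarget[k])) - R.dtol[k];
    if (v > 0) tf += R.w_dih * v * v;
  }
  return tf;
}

// [[Rcpp::export]]
double target_function_cpp(NumericMatrix coords, int nres,
                           IntegerVector grp, IntegerVector ai, IntegerVector aj,
                           NumericVector lower, NumericVector upper,
                           IntegerVector dres, IntegerVector dtyp,
                           NumericVector dtarget, NumericVector dtol,
                           NumericVector weights, double rmin) {
  Restraints R = make_restraints(nres, grp, ai, aj, lower, upper,
                                 dres, dtyp, dtarget, dtol, weights, rmin);
  std::vector<Vec3> xyz(coords.nrow());
  for (int i = 0; i < coords.nrow(); ++i) xyz[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
  NumericMatrix tors = dihedrals_from_coords_cpp(coords, nres);
  std::vector<double> phi(nres), psi(nres);
  for (int i = 0; i < nres; ++i) {
    phi[i] = (i == 0) ? 0.0 : tors(i, 0);
    psi[i] = tors(i, 1);
  }
  return tf_spatial(xyz, R) + tf_dihedral(phi, psi, R);
}

// ---------------------------------------------------------------------------
// simulated annealing in torsion space

// energy and its gradient with respect to torsions (degrees).
// Cartesian force accumulation, then the rigid-rotation chain rule with
// suffix sums over residues:
//   dE/dtheta = a . sum_k (x_k x g_k) - a . (p x sum_k g_k)
// phi_i rotates {C,O,CB,SC}_i and residues > i about the N_i->CA_i axis;
// psi_i rotates {O}_i and residues > i about the CA_i->C_i axis.
static double tf_with_grad(const std::vector<double> &phi,
                           const std::vector<double> &psi,
                           const Restraints &R,
                           std::vector<Vec3> &xyz,
                           std::vector<double> &gphi,
                           std::vector<double> &gpsi) {
  int nres = (int)phi.size();
  build_chain(phi, psi, xyz);
  int natoms = 6 * nres;
  std::vector<Vec3> g(natoms, {0, 0, 0});
  double tf = 0.0;

  int nr = (int)R.grp.size() - 1;
  for (int r = 0; r < nr; ++r) {
    int a = R.grp[r], b = R.grp[r + 1];
    if (b - a == 1) {
      Vec3 d = vsub(xyz[R.ai[a]], xyz[R.aj[a]]);
      double dist = vnorm(d);
      double coef = 0.0;
      if (dist > R.upper[r]) { double v = dist - R.upper[r]; tf += R.w_upper * v * v; coef = 2.0 * R.w_upper * v / dist; }
      else if (dist < R.lower[r]) { double v = R.lower[r] - dist; tf += R.w_lower * v * v; coef = -2.0 * R.w_lower * v / dist; }
      if (coef != 0.0) {
        Vec3 f = vscale(d, coef);
        g[R.ai[a]] = vadd(g[R.ai[a]], f);
        g[R.aj[a]] = vsub(g[R.aj[a]], f);
      }
    } else {
      double S = 0.0;
      for (int k = a; k < b; ++k) {
        double dk = vnorm(vsub(xyz[R.ai[k]], xyz[R.aj[k]]));
        S += 1.0 / (dk * dk * dk * dk * dk * dk);
      }
      double deff = std::pow(S, -1.0 / 6.0);
      double dE = 0.0;
      if (deff > R.upper[r]) { double v = deff - R.upper[r]; tf += R.w_upper * v * v; dE = 2.0 * R.w_upper * v; }
      else if (deff < R.lower[r]) { double v = R.lower[r] - deff; tf += R.w_lower * v * v; dE = -2.0 * R.w_lower * v; }
      if (dE != 0.0) {
        double d7 = std::pow(deff, 7.0);
        for (int k = a; k < b; ++k) {
          Vec3 d = vsub(xyz[R.ai[k]], xyz[R.aj[k]]);
          double dk = vnorm(d);
          double ddeff_ddk = d7 / std::pow(dk, 7.0);
          Vec3 f = vscale(d, dE * ddeff_ddk / dk);
          g[R.ai[k]] = vadd(g[R.ai[k]], f);
          g[R.aj[k]] = vsub(g[R.aj[k]], f);
        }
      }
    }
  }
  if (R.w_steric > 0) {
    double r2 = R.rmin * R.rmin;
    int ns = (int)R.steric_atoms.size();
    for (int p = 0; p < ns; ++p) {
      const Vec3 &xp = xyz[R.steric_atoms[p]];
      for (int q = p + 1; q < ns; ++q) {
        if (R.steric_res[q] - R.steric_res[p] < 2) continue;
        const Vec3 &xq = xyz[R.steric_atoms[q]];
        double dx = xp.x - xq.x, dy = xp.y - xq.y, dz = xp.z - xq.z;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < r2) {
          double dist = std::sqrt(d2);
          double v = R.rmin - dist;
          tf += R.w_steric * v * v;
          double coef = -2.0 * R.w_steric * v / dist;
          Vec3 f = {coef * dx, coef * dy, coef * dz};
          g[R.steric_atoms[p]] = vadd(g[R.steric_atoms[p]], f);
          g[R.steric_atoms[q]] = vsub(g[R.steric_atoms[q]], f);
        }
      }
    }
  }

  // suffix sums over residues
  std::vector<Vec3> Fsuf(nres + 1, {0, 0, 0}), Tsuf(nres + 1, {0, 0, 0});
  for (int r = nres - 1; r >= 0; --r) {
    Vec3 F = Fsuf[r + 1], T = Tsuf[r + 1];
    for (int s = 0; s < 6; ++s) {
      int k = 6 * r + s;
      F = vadd(F, g[k]);
      T = vadd(T, vcross(xyz[k], g[k]));
    }
    Fsuf[r] = F; Tsuf[r] = T;
  }
  std::fill(gphi.begin(), gphi.end(), 0.0);
  std::fill(gpsi.begin(), gpsi.end(), 0.0);
  for (int i = 0; i < nres; ++i) {
    Vec3 N = xyz[6 * i], CA = xyz[6 * i + 1], C = xyz[6 * i + 2];
    if (i > 0) {
      Vec3 a = vunit(vsub(CA, N));
      Vec3 F = Fsuf[i + 1], T = Tsuf[i + 1];
      for (int s = 2; s < 6; ++s) {  // C, O, CB, SC of residue i
        int k = 6 * i + s;
        F = vadd(F, g[k]);
        T = vadd(T, vcross(xyz[k], g[k]));
      }
      gphi[i] = (vdot(a, T) - vdot(a, vcross(CA, F))) * DEG;
    }
    {
      Vec3 a = vunit(vsub(C, CA));
      Vec3 F = Fsuf[i + 1], T = Tsuf[i + 1];
      int k = 6 * i + 3;  // O of residue i
      F = vadd(F, g[k]);
      T = vadd(T, vcross(xyz[k], g[k]));
      gpsi[i] = (vdot(a, T) - vdot(a, vcross(CA, F))) * DEG;
    }
  }
  // dihedral restraint terms act directly on the torsions
  for (size_t k = 0; k < R.dres.size(); ++k) {
    int i = R.dres[k];
    if (R.dtyp[k] == 0 && i == 0) continue;
    double ang = (R.dtyp[k] == 0) ? phi[i] : psi[i];
    double diff = adiff(ang, R.dtarget[k]);
    double v = std::fabs(diff) - R.dtol[k];
    if (v > 0) {
      tf += R.w_dih * v * v;
      double dd = 2.0 * R.w_dih * v * (diff > 0 ? 1.0 : -1.0);
      if (R.dtyp[k] == 0) gphi[i] += dd; else gpsi[i] += dd;
    }
  }
  return tf;
}

// numerical-check helper (exercised by the test suite)
// [[Rcpp::export]]
List tf_grad_cpp(NumericVector phi, NumericVector psi, int nres,
                 IntegerVector grp, IntegerVector ai, IntegerVector aj,
                 NumericVector lower, NumericVector upper,
                 IntegerVector dres, IntegerVector dtyp,
                 NumericVector dtarget, NumericVector dtol,
                 NumericVector weights, double rmin) {
  Restraints R = make_restraints(nres, grp, ai, aj, lower, upper,
                                 dres, dtyp, dtarget, dtol, weights, rmin);
  std::vector<double> p(phi.begin(), phi.end()), s(psi.begin(), psi.end());
  std::vector<Vec3> xyz;
  std::vector<double> gp(nres), gs(nres);
  double tf = tf_with_grad(p, s, R, xyz, gp, gs);
  return List::create(_["tf"] = tf,
                      _["gphi"] = NumericVector(gp.begin(), gp.end()),
                      _["gpsi"] = NumericVector(gs.begin(), gs.end()));
}

// [[Rcpp::export]]
List anneal_cpp(int nres,
                IntegerVector grp, IntegerVector ai, IntegerVector aj,
                NumericVector lower, NumericVector upper,
                IntegerVector dres, IntegerVector dtyp,
                NumericVector dtarget, NumericVector dtol,
                NumericVector weights, double rmin,
                int n_conf, int n_steps, int n_keep, int seed,
                double divergence_ceiling,
                NumericVector init_phi, NumericVector init_psi,
                double init_noise, double therm_noise) {
  Restraints R = make_restraints(nres, grp, ai, aj, lower, upper,
                                 dres, dtyp, dtarget, dtol, weights, rmin);
  std::vector<double> energies(n_conf);
  std::vector<std::vector<double>> all_phi(n_conf), all_psi(n_conf);
  int quench = n_steps / 2;
  // lookup of dihedral-restrained angles for goal-directed kick moves
  struct DR { int res, typ; double target, tol; };
  std::vector<DR> drs;
  for (size_t k = 0; k < R.dres.size(); ++k) {
    if (R.dtyp[k] == 0 && R.dres[k] == 0) continue;
    drs.push_back({R.dres[k], R.dtyp[k], R.dtarget[k], R.dtol[k]});
  }

  for (int c = 0; c < n_conf; ++c) {
    std::seed_seq sseq{seed, c};
    std::mt19937 rng(sseq);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::normal_distribution<double> gauss(0.0, 1.0);

    std::vector<double> phi(nres), psi(nres);
    bool seeded = init_phi.size() == nres;
    for (int i = 0; i < nres; ++i) {
      if (seeded) {
        phi[i] = init_phi[i] + gauss(rng) * init_noise;
        psi[i] = init_psi[i] + gauss(rng) * init_noise;
        while (phi[i] > 180.0) phi[i] -= 360.0;
        while (phi[i] <= -180.0) phi[i] += 360.0;
        while (psi[i] > 180.0) psi[i] -= 360.0;
        while (psi[i] <= -180.0) psi[i] += 360.0;
      } else {
        phi[i] = unif(rng) * 360.0 - 180.0;
        psi[i] = unif(rng) * 360.0 - 180.0;
      }
    }
    std::vector<Vec3> xyz;
    std::vector<double> gphi(nres), gpsi(nres);
    std::vector<double> vphi(nres, 0.0), vpsi(nres, 0.0);
    std::vector<double> msphi(nres, 0.0), mspsi(nres, 0.0);

    // phase 1 (hot): annealed torsion dynamics with RMS-normalized momentum
    // steps (effective step in degrees independent of restraint count) and
    // geometrically decaying thermal noise
    double eta0 = 1.0, eta1 = 0.05, mu = 0.9, vcap = 8.0, msdecay = 0.95;
    double noise0 = therm_noise, noise1 = 0.05;
    double tf = 0.0;
    for (int s = 0; s < n_steps; ++s) {
      double frac = (double)s / std::max(1, n_steps - 1);
      double noise = noise0 * std::pow(noise1 / noise0, frac);
      double eta = eta0 * std::pow(eta1 / eta0, frac);
      tf = tf_with_grad(phi, psi, R, xyz, gphi, gpsi);
      for (int i = 0; i < nres; ++i) {
        msphi[i] = msdecay * msphi[i] + (1 - msdecay) * gphi[i] * gphi[i];
        mspsi[i] = msdecay * mspsi[i] + (1 - msdecay) * gpsi[i] * gpsi[i];
        double sp = gphi[i] / std::sqrt(msphi[i] + 1e-10);
        double ss = gpsi[i] / std::sqrt(mspsi[i] + 1e-10);
        vphi[i] = mu * vphi[i] - eta * sp + gauss(rng) * noise;
        vpsi[i] = mu * vpsi[i] - eta * ss + gauss(rng) * noise;
        if (vphi[i] > vcap) vphi[i] = vcap; else if (vphi[i] < -vcap) vphi[i] = -vcap;
        if (vpsi[i] > vcap) vpsi[i] = vcap; else if (vpsi[i] < -vcap) vpsi[i] = -vcap;
        phi[i] += vphi[i]; psi[i] += vpsi[i];
        if (phi[i] > 180.0) phi[i] -= 360.0; else if (phi[i] <= -180.0) phi[i] += 360.0;
        if (psi[i] > 180.0) psi[i] -= 360.0; else if (psi[i] <= -180.0) psi[i] += 360.0;
      }
    }
    // phase 2 (quench): backtracking gradient descent for robust local
    // convergence
    {
      double lr = 0.0;
      std::vector<double> tphi(nres), tpsi(nres);
      tf = tf_with_grad(phi, psi, R, xyz, gphi, gpsi);
      double gmax = 1e-10;
      for (int i = 0; i < nres; ++i)
        gmax = std::max(gmax, std::max(std::fabs(gphi[i]), std::fabs(gpsi[i])));
      lr = 1.0 / gmax;  // first trial step ~1 degree at the largest gradient
      for (int it = 0; it < quench / 2; ++it) {
        bool moved = false;
        for (int bt = 0; bt < 8; ++bt) {
          for (int i = 0; i < nres; ++i) {
            double dp = -lr * gphi[i], ds = -lr * gpsi[i];
            if (dp > 5) dp = 5; else if (dp < -5) dp = -5;
            if (ds > 5) ds = 5; else if (ds < -5) ds = -5;
            tphi[i] = phi[i] + dp; tpsi[i] = psi[i] + ds;
            if (tphi[i] > 180.0) tphi[i] -= 360.0; else if (tphi[i] <= -180.0) tphi[i] += 360.0;
            if (tpsi[i] > 180.0) tpsi[i] -= 360.0; else if (tpsi[i] <= -180.0) tpsi[i] += 360.0;
          }
          build_chain(tphi, tpsi, xyz);
          double tf_try = tf_spatial(xyz, R) + tf_dihedral(tphi, tpsi, R);
          if (tf_try < tf) {
            phi = tphi; psi = tpsi;
            lr *= 1.3;
            moved = true;
            break;
          }
          lr *= 0.4;
        }
        if (!moved) break;
        tf = tf_with_grad(phi, psi, R, xyz, gphi, gpsi);
      }
    }
    // greedy single-angle polish with goal-directed kicks
    build_chain(phi, psi, xyz);
    tf = tf_spatial(xyz, R) + tf_dihedral(phi, psi, R);
    int polish = n_steps / 4;
    for (int s = 0; s < polish; ++s) {
      double mv = unif(rng);
      int k; bool do_phi; double prop;
      if (mv < 0.3 && !drs.empty()) {
        const DR &d = drs[(int)(unif(rng) * drs.size()) % drs.size()];
        k = d.res; do_phi = d.typ == 0;
        prop = d.target + gauss(rng) * 0.5 * d.tol;
      } else {
        k = (int)(unif(rng) * nres); if (k >= nres) k = nres - 1;
        do_phi = unif(rng) < 0.5;
        prop = (do_phi ? phi[k] : psi[k]) + gauss(rng) * 2.0;
      }
      std::vector<double> *ang = do_phi ? &phi : &psi;
      double old = (*ang)[k];
      while (prop > 180.0) prop -= 360.0;
      while (prop <= -180.0) prop += 360.0;
      (*ang)[k] = prop;
      build_chain(phi, psi, xyz);
      double tf_new = tf_spatial(xyz, R) + tf_dihedral(phi, psi, R);
      if (tf_new <= tf) tf = tf_new; else (*ang)[k] = old;
    }
    energies[c] = tf;
    all_phi[c] = phi;
    all_psi[c] = psi;
  }

  std::vector<int> ord(n_conf);
  for (int i = 0; i < n_conf; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return energies[a] < energies[b]; });
  int keep = std::min(n_keep, n_conf);
  List coords_out(keep);
  NumericVector kept_energy(keep);
  IntegerVector kept_idx(keep);
  for (int k = 0; k < keep; ++k) {
    int c = ord[k];
    std::vector<Vec3> xyz;
    build_chain(all_phi[c], all_psi[c], xyz);
    NumericMatrix m(6 * nres, 3);
    for (int i = 0; i < 6 * nres; ++i) {
      m(i, 0) = xyz[i].x; m(i, 1) = xyz[i].y; m(i, 2) = xyz[i].z;
    }
    coords_out[k] = m;
    kept_energy[k] = energies[c];
    kept_idx[k] = c + 1;
  }
  NumericVector all_e(energies.begin(), energies.end());
  LogicalVector diverged(n_conf);
  for (int c = 0; c < n_conf; ++c) diverged[c] = energies[c] > divergence_ceiling;
  return List::create(_["coords"] = coords_out, _["energies"] = kept_energy,
                      _["conformer"] = kept_idx, _["all_energies"] = all_e,
                      _["diverged"] = diverged);
}

// pure backtracking gradient descent over torsions (local refinement)
// [[Rcpp::export]]
List quench_cpp(NumericVector phi0, NumericVector psi0, int nres,
                IntegerVector grp, IntegerVector ai, IntegerVector aj,
                NumericVector lower, NumericVector upper,
                IntegerVector dres, IntegerVector dtyp,
                NumericVector dtarget, NumericVector dtol,
                NumericVector weights, double rmin, int iters) {
  Restraints R = make_restraints(nres, grp, ai, aj, lower, upper,
                                 dres, dtyp, dtarget, dtol, weights, rmin);
  std::vector<double> phi(phi0.begin(), phi0.end()), psi(psi0.begin(), psi0.end());
  std::vector<Vec3> xyz;
  std::vector<double> gphi(nres), gpsi(nres), tphi(nres), tpsi(nres);
  double tf = tf_with_grad(phi, psi, R, xyz, gphi, gpsi);
  double gmax = 1e-10;
  for (int i = 0; i < nres; ++i)
    gmax = std::max(gmax, std::max(std::fabs(gphi[i]), std::fabs(gpsi[i])));
  double lr = 1.0 / gmax;
  for (int it = 0; it < iters; ++it) {
    bool moved = false;
    for (int bt = 0; bt < 10; ++bt) {
      for (int i = 0; i < nres; ++i) {
        double dp = -lr * gphi[i], ds = -lr * gpsi[i];
        if (dp > 5) dp = 5; else if (dp < -5) dp = -5;
        if (ds > 5) ds = 5; else if (ds < -5) ds = -5;
        tphi[i] = phi[i] + dp; tpsi[i] = psi[i] + ds;
        if (tphi[i] > 180.0) tphi[i] -= 360.0; else if (tphi[i] <= -180.0) tphi[i] += 360.0;
        if (tpsi[i] > 180.0) tpsi[i] -= 360.0; else if (tpsi[i] <= -180.0) tpsi[i] += 360.0;
      }
      build_chain(tphi, tpsi, xyz);
      double tf_try = tf_spatial(xyz, R) + tf_dihedral(tphi, tpsi, R);
      if (tf_try < tf) {
        phi = tphi; psi = tpsi; tf = tf_try;
        lr *= 1.3;
        moved = true;
        break;
      }
      lr *= 0.4;
    }
    if (!moved) break;
    tf = tf_with_grad(phi, psi, R, xyz, gphi, gpsi);
  }
  build_chain(phi, psi, xyz);
  NumericMatrix out(6 * nres, 3);
  for (int i = 0; i < 6 * nres; ++i) {
    out(i, 0) = xyz[i].x; out(i, 1) = xyz[i].y; out(i, 2) = xyz[i].z;
  }
  return List::create(_["coords"] = out, _["tf"] = tf,
                      _["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["psi"] = NumericVector(psi.begin(), psi.end()));
}

static inline double trilinear(const double *g, int nx, int ny, int nz,
                               const double *origin, double voxel,
                               double x, double y, double z, bool *inside);
static void map_gradient(const double *g, int nx, int ny, int nz,
                         const double *origin, double voxel,
                         double x, double y, double z, double h, Vec3 &grad);

// Joint local minimization of E = TF(torsions) + w_map * sum_k -rho(op_k w)
// over protomer torsions and rigid pose, by backtracking gradient descent.
// World coords: w = Rm * (x - centroid(x)) + cen + t; every symmetry image
// contributes map energy and its force is folded back to the local frame
// (strict symmetry by construction). The backbone N/CA/C/O atoms carry the
// map term.
// [[Rcpp::export]]
List quench_map_cpp(NumericVector phi0, NumericVector psi0,
                    NumericMatrix Rm0, NumericVector cen0, NumericVector t0,
                    IntegerVector grp, IntegerVector ai, IntegerVector aj,
                    NumericVector lower, NumericVector upper,
                    IntegerVector dres, IntegerVector dtyp,
                    NumericVector dtarget, NumericVector dtol,
                    NumericVector weights, double rmin,
                    NumericVector grid, IntegerVector dims, NumericVector origin,
                    double voxel, NumericMatrix ops, double w_map, int iters) {
  int nres = phi0.size();
  int natoms = 6 * nres;
  Restraints R = make_restraints(nres, grp, ai, aj, lower, upper,
                                 dres, dtyp, dtarget, dtol, weights, rmin);
  int nops = ops.nrow() / 3;
  std::vector<double> phi(phi0.begin(), phi0.end()), psi(psi0.begin(), psi0.end());
  double Rm[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) Rm[3 * r + c] = Rm0(r, c);
  double tvec[3] = {t0[0], t0[1], t0[2]};
  double cen[3] = {cen0[0], cen0[1], cen0[2]};

  std::vector<Vec3> xyz;
  std::vector<double> gphi(nres), gpsi(nres);
  std::vector<Vec3> gmap(natoms);

  // energy + full gradient at a state
  auto eval = [&](std::vector<double> &ph, std::vector<double> &ps,
                  double *Rmat, double *tv, double wm,
                  std::vector<double> *gp, std::vector<double> *gs,
                  Vec3 *Fnet, Vec3 *Tnet, double *e_tf, double *e_map) {
    double tf;
    if (gp) tf = tf_with_grad(ph, ps, R, xyz, *gp, *gs);
    else { build_chain(ph, ps, xyz); tf = tf_spatial(xyz, R) + tf_dihedral(ph, ps, R); }
    Vec3 c = {0, 0, 0};
    for (auto &p : xyz) c = vadd(c, p);
    c = vscale(c, 1.0 / natoms);
    double emap = 0.0;
    if (Fnet) { *Fnet = {0, 0, 0}; *Tnet = {0, 0, 0}; }
    if (gp) for (int i = 0; i < natoms; ++i) gmap[i] = {0, 0, 0};
    for (int i = 0; i < natoms; ++i) {
      if (i % 6 > 3) continue;
      Vec3 d = vsub(xyz[i], c);
      double wx = Rmat[0] * d.x + Rmat[1] * d.y + Rmat[2] * d.z + cen[0] + tv[0];
      double wy = Rmat[3] * d.x + Rmat[4] * d.y + Rmat[5] * d.z + cen[1] + tv[1];
      double wz = Rmat[6] * d.x + Rmat[7] * d.y + Rmat[8] * d.z + cen[2] + tv[2];
      for (int k = 0; k < nops; ++k) {
        double ox = ops(3 * k, 0) * wx + ops(3 * k, 1) * wy + ops(3 * k, 2) * wz + ops(3 * k, 3);
        double oy = ops(3 * k + 1, 0) * wx + ops(3 * k + 1, 1) * wy + ops(3 * k + 1, 2) * wz + ops(3 * k + 1, 3);
        double oz = ops(3 * k + 2, 0) * wx + ops(3 * k + 2, 1) * wy + ops(3 * k + 2, 2) * wz + ops(3 * k + 2, 3);
        emap -= trilinear(grid.begin(), dims[0], dims[1], dims[2], origin.begin(),
                          voxel, ox, oy, oz, nullptr);
        if (gp) {
          Vec3 gw;
          map_gradient(grid.begin(), dims[0], dims[1], dims[2], origin.begin(),
                       voxel, ox, oy, oz, 0.5 * voxel, gw);
          Vec3 gE = vscale(gw, -wm);  // dE/d(op w)
          Vec3 gw_pre = {ops(3 * k, 0) * gE.x + ops(3 * k + 1, 0) * gE.y + ops(3 * k + 2, 0) * gE.z,
                         ops(3 * k, 1) * gE.x + ops(3 * k + 1, 1) * gE.y + ops(3 * k + 2, 1) * gE.z,
                         ops(3 * k, 2) * gE.x + ops(3 * k + 1, 2) * gE.y + ops(3 * k + 2, 2) * gE.z};
          Fnet->x += gw_pre.x; Fnet->y += gw_pre.y; Fnet->z += gw_pre.z;
          Vec3 arm = {wx - cen[0] - tv[0], wy - cen[1] - tv[1], wz - cen[2] - tv[2]};
          Vec3 tq = vcross(arm, gw_pre);
          Tnet->x += tq.x; Tnet->y += tq.y; Tnet->z += tq.z;
          Vec3 gl = {Rmat[0] * gw_pre.x + Rmat[3] * gw_pre.y + Rmat[6] * gw_pre.z,
                     Rmat[1] * gw_pre.x + Rmat[4] * gw_pre.y + Rmat[7] * gw_pre.z,
                     Rmat[2] * gw_pre.x + Rmat[5] * gw_pre.y + Rmat[8] * gw_pre.z};
          gmap[i] = gl;
        }
      }
    }
    if (gp) {
      // torsion gradient of the map term via suffix sums
      std::vector<Vec3> Fsuf(nres + 1, {0, 0, 0}), Tsuf(nres + 1, {0, 0, 0});
      for (int r = nres - 1; r >= 0; --r) {
        Vec3 F = Fsuf[r + 1], T = Tsuf[r + 1];
        for (int sl = 0; sl < 6; ++sl) {
          int k = 6 * r + sl;
          F = vadd(F, gmap[k]);
          T = vadd(T, vcross(xyz[k], gmap[k]));
        }
        Fsuf[r] = F; Tsuf[r] = T;
      }
      for (int i = 0; i < nres; ++i) {
        Vec3 N = xyz[6 * i], CA = xyz[6 * i + 1], C = xyz[6 * i + 2];
        if (i > 0) {
          Vec3 a = vunit(vsub(CA, N));
          Vec3 F = Fsuf[i + 1], T = Tsuf[i + 1];
          for (int sl = 2; sl < 6; ++sl) {
            int k = 6 * i + sl;
            F = vadd(F, gmap[k]);
            T = vadd(T, vcross(xyz[k], gmap[k]));
          }
          (*gp)[i] += (vdot(a, T) - vdot(a, vcross(CA, F))) * DEG;
        }
        Vec3 a = vunit(vsub(C, CA));
        Vec3 F = Fsuf[i + 1], T = Tsuf[i + 1];
        int k = 6 * i + 3;
        F = vadd(F, gmap[k]);
        T = vadd(T, vcross(xyz[k], gmap[k]));
        (*gs)[i] += (vdot(a, T) - vdot(a, vcross(CA, F))) * DEG;
      }
    }
    *e_tf = tf; *e_map = emap;
    return tf + wm * emap;
  };

  // auto-calibrate w_map (negative sentinel): equal energy magnitudes
  double etf, emap;
  {
    std::vector<double> gp(nres), gs(nres);
    Vec3 F, T;
    eval(phi, psi, Rm, tvec, 0.0, &gp, &gs, &F, &T, &etf, &emap);
    if (w_map < 0)
      w_map = std::max(1.0, std::fabs(etf)) / std::max(1e-6, std::fabs(emap));
  }

  Vec3 Fnet, Tnet;
  double E = eval(phi, psi, Rm, tvec, w_map, &gphi, &gpsi, &Fnet, &Tnet, &etf, &emap);
  double lr = 0.0;
  {
    double gmax = 1e-10;
    for (int i = 0; i < nres; ++i)
      gmax = std::max(gmax, std::max(std::fabs(gphi[i]), std::fabs(gpsi[i])));
    lr = 1.0 / gmax;
  }
  std::vector<double> tphi(nres), tpsi(nres);
  for (int it = 0; it < iters; ++it) {
    bool moved = false;
    for (int bt = 0; bt < 10; ++bt) {
      // torsion block
      for (int i = 0; i < nres; ++i) {
        double dp = -lr * gphi[i], ds = -lr * gpsi[i];
        if (dp > 5) dp = 5; else if (dp < -5) dp = -5;
        if (ds > 5) ds = 5; else if (ds < -5) ds = -5;
        tphi[i] = phi[i] + dp; tpsi[i] = psi[i] + ds;
        if (tphi[i] > 180.0) tphi[i] -= 360.0; else if (tphi[i] <= -180.0) tphi[i] += 360.0;
        if (tpsi[i] > 180.0) tpsi[i] -= 360.0; else if (tpsi[i] <= -180.0) tpsi[i] += 360.0;
      }
      // pose block: translation along -Fnet, rotation about -Tnet
      double nt[3] = {tvec[0], tvec[1], tvec[2]};
      double nR[9];
      std::copy(Rm, Rm + 9, nR);
      double fn = vnorm(Fnet);
      if (fn > 1e-12) {
        double st = std::min(lr * fn, 0.3) / fn;   // cap 0.3 A
        nt[0] -= st * Fnet.x; nt[1] -= st * Fnet.y; nt[2] -= st * Fnet.z;
      }
      double tn = vnorm(Tnet);
      if (tn > 1e-12) {
        double ang = std::min(lr * tn, 0.01);       // cap 0.01 rad
        Vec3 axn = vscale(Tnet, -1.0 / tn);
        double ca2 = std::cos(ang), sa = std::sin(ang), C1 = 1 - ca2;
        double Q[9] = {ca2 + axn.x * axn.x * C1, axn.x * axn.y * C1 - axn.z * sa, axn.x * axn.z * C1 + axn.y * sa,
                       axn.y * axn.x * C1 + axn.z * sa, ca2 + axn.y * axn.y * C1, axn.y * axn.z * C1 - axn.x * sa,
                       axn.z * axn.x * C1 - axn.y * sa, axn.z * axn.y * C1 + axn.x * sa, ca2 + axn.z * axn.z * C1};
        for (int r = 0; r < 3; ++r)
          for (int c2 = 0; c2 < 3; ++c2)
            nR[3 * r + c2] = Q[3 * r] * Rm[c2] + Q[3 * r + 1] * Rm[3 + c2] + Q[3 * r + 2] * Rm[6 + c2];
      }
      double e1, e2;
      double Etry = eval(tphi, tpsi, nR, nt, w_map, nullptr, nullptr, nullptr,
                         nullptr, &e1, &e2);
      if (Etry < E) {
        phi = tphi; psi = tpsi;
        std::copy(nR, nR + 9, Rm);
        tvec[0] = nt[0]; tvec[1] = nt[1]; tvec[2] = nt[2];
        E = Etry;
        lr *= 1.3;
        moved = true;
        break;
      }
      lr *= 0.4;
    }
    if (!moved) break;
    E = eval(phi, psi, Rm, tvec, w_map, &gphi, &gpsi, &Fnet, &Tnet, &etf, &emap);
  }

  build_chain(phi, psi, xyz);
  Vec3 c = {0, 0, 0};
  for (auto &p : xyz) c = vadd(c, p);
  c = vscale(c, 1.0 / natoms);
  NumericMatrix out(natoms, 3);
  for (int i = 0; i < natoms; ++i) {
    Vec3 d = vsub(xyz[i], c);
    out(i, 0) = Rm[0] * d.x + Rm[1] * d.y + Rm[2] * d.z + cen[0] + tvec[0];
    out(i, 1) = Rm[3] * d.x + Rm[4] * d.y + Rm[5] * d.z + cen[1] + tvec[1];
    out(i, 2) = Rm[6] * d.x + Rm[7] * d.y + Rm[8] * d.z + cen[2] + tvec[2];
  }
  return List::create(_["coords"] = out, _["energy"] = E, _["tf"] = etf,
                      _["emap"] = emap, _["w_map"] = w_map);
}

// Map-aware restrained annealing: like anneal_cpp but the energy is
// E = TF + w_map * sum_ops -rho over backbone N/CA/C/O image atoms, with a
// fixed pose during the hot phase and a joint torsion+pose backtracking
// quench. Conformers start from the given torsions plus noise. Used by the
// final symmetry-replicated refinement stage.
// [[Rcpp::export]]
List anneal_map_cpp(NumericVector phi0, NumericVector psi0,
                    NumericMatrix Rm0, NumericVector cen0, NumericVector t0,
                    IntegerVector grp, IntegerVector ai, IntegerVector aj,
                    NumericVector lower, NumericVector upper,
                    IntegerVector dres, IntegerVector dtyp,
                    NumericVector dtarget, NumericVector dtol,
                    NumericVector weights, double rmin,
                    NumericVector grid, IntegerVector dims, NumericVector origin,
                    double voxel, NumericMatrix ops, double w_map,
                    int n_conf, int n_steps, int n_keep, int seed,
                    double init_noise, double therm_noise) {
  int nres = phi0.size();
  int natoms = 6 * nres;
  Restraints R = make_restraints(nres, grp, ai, aj, lower, upper,
                                 dres, dtyp, dtarget, dtol, weights, rmin);
  int nops = ops.nrow() / 3;
  double Rm[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) Rm[3 * r + c] = Rm0(r, c);
  double cen[3] = {cen0[0], cen0[1], cen0[2]};

  std::vector<Vec3> xyz;
  // map energy and its local-frame force for a fixed pose (no pose grads)
  auto map_term = [&](const double *Rmat, const double *tv,
                      std::vector<Vec3> *gmap) {
    Vec3 c = {0, 0, 0};
    for (auto &p : xyz) c = vadd(c, p);
    c = vscale(c, 1.0 / natoms);
    double emap = 0.0;
    for (int i = 0; i < natoms; ++i) {
      if (i % 6 > 3) continue;
      Vec3 d = vsub(xyz[i], c);
      double wx = Rmat[0] * d.x + Rmat[1] * d.y + Rmat[2] * d.z + cen[0] + tv[0];
      double wy = Rmat[3] * d.x + Rmat[4] * d.y + Rmat[5] * d.z + cen[1] + tv[1];
      double wz = Rmat[6] * d.x + Rmat[7] * d.y + Rmat[8] * d.z + cen[2] + tv[2];
      for (int k = 0; k < nops; ++k) {
        double ox = ops(3 * k, 0) * wx + ops(3 * k, 1) * wy + ops(3 * k, 2) * wz + ops(3 * k, 3);
        double oy = ops(3 * k + 1, 0) * wx + ops(3 * k + 1, 1) * wy + ops(3 * k + 1, 2) * wz + ops(3 * k + 1, 3);
        double oz = ops(3 * k + 2, 0) * wx + ops(3 * k + 2, 1) * wy + ops(3 * k + 2, 2) * wz + ops(3 * k + 2, 3);
        emap -= trilinear(grid.begin(), dims[0], dims[1], dims[2], origin.begin(),
                          voxel, ox, oy, oz, nullptr);
        if (gmap) {
          Vec3 gw;
          map_gradient(grid.begin(), dims[0], dims[1], dims[2], origin.begin(),
                       voxel, ox, oy, oz, 0.5 * voxel, gw);
          Vec3 gE = vscale(gw, -w_map);
          Vec3 gw_pre = {ops(3 * k, 0) * gE.x + ops(3 * k + 1, 0) * gE.y + ops(3 * k + 2, 0) * gE.z,
                         ops(3 * k, 1) * gE.x + ops(3 * k + 1, 1) * gE.y + ops(3 * k + 2, 1) * gE.z,
                         ops(3 * k, 2) * gE.x + ops(3 * k + 1, 2) * gE.y + ops(3 * k + 2, 2) * gE.z};
          Vec3 gl = {Rmat[0] * gw_pre.x + Rmat[3] * gw_pre.y + Rmat[6] * gw_pre.z,
                     Rmat[1] * gw_pre.x + Rmat[4] * gw_pre.y + Rmat[7] * gw_pre.z,
                     Rmat[2] * gw_pre.x + Rmat[5] * gw_pre.y + Rmat[8] * gw_pre.z};
          (*gmap)[i] = vadd((*gmap)[i], gl);
        }
      }
    }
    return emap;
  };
  // fold a local-frame per-atom map force into torsion gradients
  auto fold_map_grad = [&](const std::vector<Vec3> &gmap,
                           std::vector<double> &gphi, std::vector<double> &gpsi) {
    std::vector<Vec3> Fsuf(nres + 1, {0, 0, 0}), Tsuf(nres + 1, {0, 0, 0});
    for (int r = nres - 1; r >= 0; --r) {
      Vec3 F = Fsuf[r + 1], T = Tsuf[r + 1];
      for (int sl = 0; sl < 6; ++sl) {
        int k = 6 * r + sl;
        F = vadd(F, gmap[k]);
        T = vadd(T, vcross(xyz[k], gmap[k]));
      }
      Fsuf[r] = F; Tsuf[r] = T;
    }
    for (int i = 0; i < nres; ++i) {
      Vec3 N = xyz[6 * i], CA = xyz[6 * i + 1], C = xyz[6 * i + 2];
      if (i > 0) {
        Vec3 a = vunit(vsub(CA, N));
        Vec3 F = Fsuf[i + 1], T = Tsuf[i + 1];
        for (int sl = 2; sl < 6; ++sl) {
          int k = 6 * i + sl;
          F = vadd(F, gmap[k]);
          T = vadd(T, vcross(xyz[k], gmap[k]));
        }
        gphi[i] += (vdot(a, T) - vdot(a, vcross(CA, F))) * DEG;
      }
      Vec3 a = vunit(vsub(C, CA));
      Vec3 F = Fsuf[i + 1], T = Tsuf[i + 1];
      int k = 6 * i + 3;
      F = vadd(F, gmap[k]);
      T = vadd(T, vcross(xyz[k], gmap[k]));
      gpsi[i] += (vdot(a, T) - vdot(a, vcross(CA, F))) * DEG;
    }
  };

  std::vector<double> energies(n_conf), tfs(n_conf);
  std::vector<std::vector<double>> all_phi(n_conf), all_psi(n_conf);

  for (int cidx = 0; cidx < n_conf; ++cidx) {
    std::seed_seq sseq{seed, cidx};
    std::mt19937 rng(sseq);
    std::normal_distribution<double> gauss(0.0, 1.0);
    std::vector<double> phi(nres), psi(nres);
    for (int i = 0; i < nres; ++i) {
      phi[i] = phi0[i] + gauss(rng) * init_noise;
      psi[i] = psi0[i] + gauss(rng) * init_noise;
      while (phi[i] > 180.0) phi[i] -= 360.0;
      while (phi[i] <= -180.0) phi[i] += 360.0;
      while (psi[i] > 180.0) psi[i] -= 360.0;
      while (psi[i] <= -180.0) psi[i] += 360.0;
    }
    std::vector<double> gphi(nres), gpsi(nres);
    std::vector<double> vphi(nres, 0.0), vpsi(nres, 0.0);
    std::vector<double> msphi(nres, 0.0), mspsi(nres, 0.0);
    std::vector<Vec3> gmap(natoms);
    double tvec[3] = {t0[0], t0[1], t0[2]};

    double eta0 = 0.8, eta1 = 0.05, mu = 0.9, vcap = 5.0;
    for (int s = 0; s < n_steps; ++s) {
      double frac = (double)s / std::max(1, n_steps - 1);
      double noise = therm_noise * std::pow(0.05 / std::max(therm_noise, 0.05), frac);
      double eta = eta0 * std::pow(eta1 / eta0, frac);
      tf_with_grad(phi, psi, R, xyz, gphi, gpsi);
      std::fill(gmap.begin(), gmap.end(), Vec3{0, 0, 0});
      map_term(Rm, tvec, &gmap);
      fold_map_grad(gmap, gphi, gpsi);
      for (int i = 0; i < nres; ++i) {
        msphi[i] = 0.95 * msphi[i] + 0.05 * gphi[i] * gphi[i];
        mspsi[i] = 0.95 * mspsi[i] + 0.05 * gpsi[i] * gpsi[i];
        vphi[i] = mu * vphi[i] - eta * gphi[i] / std::sqrt(msphi[i] + 1e-10) + gauss(rng) * noise;
        vpsi[i] = mu * vpsi[i] - eta * gpsi[i] / std::sqrt(mspsi[i] + 1e-10) + gauss(rng) * noise;
        if (vphi[i] > vcap) vphi[i] = vcap; else if (vphi[i] < -vcap) vphi[i] = -vcap;
        if (vpsi[i] > vcap) vpsi[i] = vcap; else if (vpsi[i] < -vcap) vpsi[i] = -vcap;
        phi[i] += vphi[i]; psi[i] += vpsi[i];
        if (phi[i] > 180.0) phi[i] -= 360.0; else if (phi[i] <= -180.0) phi[i] += 360.0;
        if (psi[i] > 180.0) psi[i] -= 360.0; else if (psi[i] <= -180.0) psi[i] += 360.0;
      }
    }
    all_phi[cidx] = phi;
    all_psi[cidx] = psi;
    // combined energy for ranking (quench happens in R via quench_map_cpp)
    build_chain(phi, psi, xyz);
    double tf = tf_spatial(xyz, R) + tf_dihedral(phi, psi, R);
    double emap = map_term(Rm, tvec, nullptr);
    energies[cidx] = tf + w_map * emap;
    tfs[cidx] = tf;
  }
  std::vector<int> ord(n_conf);
  for (int i = 0; i < n_conf; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return energies[a] < energies[b]; });
  int keep = std::min(n_keep, n_conf);
  List phis(keep), psis(keep);
  NumericVector kept_E(keep), kept_tf(keep);
  for (int k = 0; k < keep; ++k) {
    phis[k] = NumericVector(all_phi[ord[k]].begin(), all_phi[ord[k]].end());
    psis[k] = NumericVector(all_psi[ord[k]].begin(), all_psi[ord[k]].end());
    kept_E[k] = energies[ord[k]];
    kept_tf[k] = tfs[ord[k]];
  }
  return List::create(_["phi"] = phis, _["psi"] = psis,
                      _["energy"] = kept_E, _["tf"] = kept_tf);
}

// ---------------------------------------------------------------------------
// density maps

// [[Rcpp::export]]
NumericVector simulate_map_cpp(NumericMatrix coords, IntegerVector dims,
                               NumericVector origin, double voxel,
                               double sigma, double cutoff) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector grid(nx * ny * nz);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  int w = (int)std::ceil(cutoff * sigma / voxel);
  for (int a = 0; a < coords.nrow(); ++a) {
    double x = coords(a, 0), y = coords(a, 1), z = coords(a, 2);
    int ix0 = (int)std::floor((x - origin[0]) / voxel);
    int iy0 = (int)std::floor((y - origin[1]) / voxel);
    int iz0 = (int)std::floor((z - origin[2]) / voxel);
    for (int iz = std::max(0, iz0 - w); iz <= std::min(nz - 1, iz0 + w); ++iz) {
      double dz = origin[2] + iz * voxel - z;
      for (int iy = std::max(0, iy0 - w); iy <= std::min(ny - 1, iy0 + w); ++iy) {
        double dy = origin[1] + iy * voxel - y;
        double dyz = dy * dy + dz * dz;
        for (int ix = std::max(0, ix0 - w); ix <= std::min(nx - 1, ix0 + w); ++ix) {
          double dx = origin[0] + ix * voxel - x;
          grid[ix + nx * (iy + (R_xlen_t)ny * iz)] += std::exp(-(dx * dx + dyz) * inv2s2);
        }
      }
    }
  }
  return grid;
}

// nonzero voxel indices (1-based linear) and values for a small atom set
// [[Rcpp::export]]
List gauss_local_cpp(NumericMatrix coords, IntegerVector dims,
                     NumericVector origin, double voxel,
                     double sigma, double cutoff) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  // bounding box of atoms +/- cutoff*sigma
  double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
  for (int a = 0; a < coords.nrow(); ++a)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], coords(a, d));
      hi[d] = std::max(hi[d], coords(a, d));
    }
  double pad = cutoff * sigma;
  int i0 = std::max(0, (int)std::floor((lo[0] - pad - origin[0]) / voxel));
  int j0 = std::max(0, (int)std::floor((lo[1] - pad - origin[1]) / voxel));
  int k0 = std::max(0, (int)std::floor((lo[2] - pad - origin[2]) / voxel));
  int i1 = std::min(nx - 1, (int)std::ceil((hi[0] + pad - origin[0]) / voxel));
  int j1 = std::min(ny - 1, (int)std::ceil((hi[1] + pad - origin[1]) / voxel));
  int k1 = std::min(nz - 1, (int)std::ceil((hi[2] + pad - origin[2]) / voxel));
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  std::vector<double> val;
  std::vector<double> idx;
  for (int kz = k0; kz <= k1; ++kz)
    for (int jy = j0; jy <= j1; ++jy)
      for (int ix = i0; ix <= i1; ++ix) {
        double gx = origin[0] + ix * voxel, gy = origin[1] + jy * voxel,
               gz = origin[2] + kz * voxel;
        double v = 0.0;
        for (int a = 0; a < coords.nrow(); ++a) {
          double dx = gx - coords(a, 0), dy = gy - coords(a, 1), dz = gz - coords(a, 2);
          v += std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
        }
        if (v > 0) {
          val.push_back(v);
          idx.push_back(1.0 + ix + nx * (jy + (double)ny * kz));
        }
      }
  return List::create(_["idx"] = NumericVector(idx.begin(), idx.end()),
                      _["val"] = NumericVector(val.begin(), val.end()));
}

static inline double trilinear(const double *g, int nx, int ny, int nz,
                               const double *origin, double voxel,
                               double x, double y, double z, bool *inside) {
  double fx = (x - origin[0]) / voxel, fy = (y - origin[1]) / voxel, fz = (z - origin[2]) / voxel;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy), iz = (int)std::floor(fz);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 || iz >= nz - 1) {
    if (inside) *inside = false;
    return 0.0;
  }
  if (inside) *inside = true;
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  auto G = [&](int a, int b, int c) { return g[(ix + a) + nx * ((iy + b) + (R_xlen_t)ny * (iz + c))]; };
  double c00 = G(0, 0, 0) * (1 - tx) + G(1, 0, 0) * tx;
  double c10 = G(0, 1, 0) * (1 - tx) + G(1, 1, 0) * tx;
  double c01 = G(0, 0, 1) * (1 - tx) + G(1, 0, 1) * tx;
  double c11 = G(0, 1, 1) * (1 - tx) + G(1, 1, 1) * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// [[Rcpp::export]]
NumericVector interp_map_cpp(NumericVector grid, IntegerVector dims,
                             NumericVector origin, double voxel, NumericMatrix pts) {
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trilinear(grid.begin(), dims[0], dims[1], dims[2], origin.begin(),
                       voxel, pts(i, 0), pts(i, 1), pts(i, 2), nullptr);
  return out;
}

static void map_gradient(const double *g, int nx, int ny, int nz,
                         const double *origin, double voxel,
                         double x, double y, double z, double h, Vec3 &grad) {
  grad.x = (trilinear(g, nx, ny, nz, origin, voxel, x + h, y, z, nullptr) -
            trilinear(g, nx, ny, nz, origin, voxel, x - h, y, z, nullptr)) / (2 * h);
  grad.y = (trilinear(g, nx, ny, nz, origin, voxel, x, y + h, z, nullptr) -
            trilinear(g, nx, ny, nz, origin, voxel, x, y - h, z, nullptr)) / (2 * h);
  grad.z = (trilinear(g, nx, ny, nz, origin, voxel, x, y, z + h, nullptr) -
            trilinear(g, nx, ny, nz, origin, voxel, x, y, z - h, nullptr)) / (2 * h);
}

// ---------------------------------------------------------------------------
// flexible fitting: gradient flow up the density with an elastic network
// tether to the starting conformation. Returns snapshots every `every` steps
// (snapshot 1 = input) so the caller can pick the best-correlating state.

// [[Rcpp::export]]
List flexfit_cpp(NumericMatrix coords, NumericVector grid, IntegerVector dims,
                 NumericVector origin, double voxel,
                 IntegerVector ei, IntegerVector ej, NumericVector ed,
                 NumericVector ek, double w_map, int n_steps, double step,
                 int every) {
  int n = coords.nrow();
  std::vector<Vec3> x(n);
  for (int i = 0; i < n; ++i) x[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
  int npairs = ei.size();
  // normalize map gradient scale: use max grid value
  double gmax = 0.0;
  for (R_xlen_t i = 0; i < grid.size(); ++i) gmax = std::max(gmax, grid[i]);
  if (gmax <= 0) gmax = 1.0;
  List snaps;
  std::vector<Vec3> force(n);
  for (int s = 0; s <= n_steps; ++s) {
    if (s % every == 0 || s == n_steps) {
      NumericMatrix m(n, 3);
      for (int i = 0; i < n; ++i) { m(i, 0) = x[i].x; m(i, 1) = x[i].y; m(i, 2) = x[i].z; }
      snaps.push_back(m);
    }
    if (s == n_steps) break;
    for (int i = 0; i < n; ++i) {
      Vec3 g;
      map_gradient(grid.begin(), dims[0], dims[1], dims[2], origin.begin(),
                   voxel, x[i].x, x[i].y, x[i].z, 0.5 * voxel, g);
      force[i] = vscale(g, w_map / gmax * voxel);
    }
    for (int p = 0; p < npairs; ++p) {
      Vec3 d = vsub(x[ej[p]], x[ei[p]]);
      double dist = vnorm(d);
      if (dist < 1e-9) continue;
      double f = ek[p] * (dist - ed[p]) / dist;
      force[ei[p]] = vadd(force[ei[p]], vscale(d, f));
      force[ej[p]] = vsub(force[ej[p]], vscale(d, f));
    }
    for (int i = 0; i < n; ++i) {
      double fn = vnorm(force[i]);
      double cap = 0.5;  // max displacement per step, Angstrom
      double sc = step;
      if (fn * step > cap) sc = cap / fn;
      x[i] = vadd(x[i], vscale(force[i], sc));
    }
    // keep the trajectory near the ideal-geometry manifold throughout
    if (s % 5 == 4) regularize_core(x, n / 6, 10);
  }
  return snaps;
}

// enforce ideal local covalent geometry (bond lengths plus the 1-3
// distances fixed by the ideal bond angles, and the trans-peptide CA-CA
// distance) by iterative pair projection; keeps coordinates close to the
// ideal-geometry torsion manifold so torsion extraction is faithful
static void regularize_core(std::vector<Vec3> &x, int nres, int sweeps) {
  struct Bond { int a, b; double d; };
  std::vector<Bond> bonds;
  auto d13 = [](double a, double b, double ang) {
    return std::sqrt(a * a + b * b - 2.0 * a * b * std::cos(ang * DEG));
  };
  for (int i = 0; i < nres; ++i) {
    bonds.push_back({6 * i, 6 * i + 1, B_NCA});
    bonds.push_back({6 * i + 1, 6 * i + 2, B_CAC});
    bonds.push_back({6 * i + 2, 6 * i + 3, B_CO});
    bonds.push_back({6 * i + 1, 6 * i + 4, B_CACB});
    bonds.push_back({6 * i + 1, 6 * i + 5, B_CASC});
    bonds.push_back({6 * i + 4, 6 * i + 5, B_CASC - B_CACB});
    // angle-fixing 1-3 distances
    bonds.push_back({6 * i, 6 * i + 2, d13(B_NCA, B_CAC, A_NCAC)});          // N-C
    bonds.push_back({6 * i + 1, 6 * i + 3, d13(B_CAC, B_CO, A_CACO)});       // CA-O
    bonds.push_back({6 * i, 6 * i + 4, d13(B_NCA, B_CACB, 110.4)});          // N-CB
    bonds.push_back({6 * i + 2, 6 * i + 4, d13(B_CAC, B_CACB, 110.6)});      // C-CB
    if (i + 1 < nres) {
      bonds.push_back({6 * i + 2, 6 * (i + 1), B_CN});
      bonds.push_back({6 * i + 1, 6 * (i + 1), d13(B_CAC, B_CN, A_CACN)});   // CA-N'
      bonds.push_back({6 * i + 2, 6 * (i + 1) + 1, d13(B_CN, B_NCA, A_CNCA)}); // C-CA'
      bonds.push_back({6 * i + 3, 6 * (i + 1), d13(B_CO, B_CN, 360.0 - A_CACO - A_CACN)}); // O-N'
      bonds.push_back({6 * i + 1, 6 * (i + 1) + 1, 3.80});                   // CA-CA' (trans)
    }
  }
  for (int s = 0; s < sweeps; ++s) {
    for (auto &b : bonds) {
      Vec3 d = vsub(x[b.b], x[b.a]);
      double dist = vnorm(d);
      if (dist < 1e-9) continue;
      double corr = 0.5 * (dist - b.d) / dist;
      x[b.a] = vadd(x[b.a], vscale(d, corr));
      x[b.b] = vsub(x[b.b], vscale(d, corr));
    }
  }
}

// [[Rcpp::export]]
NumericMatrix regularize_bonds_cpp(NumericMatrix coords, int nres, int sweeps) {
  int n = coords.nrow();
  std::vector<Vec3> x(n);
  for (int i = 0; i < n; ++i) x[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
  regularize_core(x, nres, sweeps);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i].x; out(i, 1) = x[i].y; out(i, 2) = x[i].z; }
  return out;
}

// minimum distance between atoms separated by >= seq_sep residues
// [[Rcpp::export]]
double min_nonbonded_cpp(NumericMatrix coords, int nres, int seq_sep) {
  double best = 1e30;
  int n = coords.nrow();
  for (int i = 0; i < n; ++i) {
    int ri = i / 6;
    for (int j = i + 1; j < n; ++j) {
      if (j / 6 - ri < seq_sep) continue;
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
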