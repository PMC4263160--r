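// Core kernels: Ewald lattice sums for the charge-pair / point-dipole
// representation of field-polarized prolate spheroids, the Metropolis MC
// loop, open-boundary direct sums for finite aggregates, and a brute-force
// periodic image-sum oracle used only by the test suite.
//
// Reduced units throughout: lengths in units of the short semi-axis R
// (R is still carried explicitly so callers may use other scales), energies
// in kT. The reduced pair energy U* = Gamma * sum Z_i Z_j / (r_ij / 2R) is
// implemented as a plain Coulomb sum with site charges +/- q*,
// q*^2 = 2 * Gamma * R.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <random>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const double PI_ = 3.14159265358979323846;

static inline double wrap0L(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}
static inline double minimg(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

// ---------------------------------------------------------------------------
// Ewald context
// ---------------------------------------------------------------------------

struct EwaldCtx {
  // geometry / physics
  int N;                 // particles
  int mode;              // 0 = charge_pair, 1 = point_dipole
  double Lx, Ly, Lz, V;
  double R, rho, d;
  double q;              // site charge magnitude, q^2 = 2*Gamma*R
  double q2;
  double mu2;            // squared reduced dipole moment (2 q d)^2
  bool live;             // false when Gamma == 0 or d == 0: no electrostatics

  // splitting
  double alpha, rc, rc2;

  // k-space
  int nmx, nmy, nmz;
  std::vector<int> inx, iny, inz;     // integer indices, nx >= 0 half space
  std::vector<double> kcoef;          // includes factor 2, 2pi/V, gaussian/k^2
                                      // (and mu2*kz^2 in dipole mode)
  std::vector<cplx> S;                // structure factor (charge weighted in
                                      // mode 0, unit weighted in mode 1)
  std::vector<cplx> dS;               // scratch for the last proposed move

  // constant (configuration independent) terms
  double Econst;

  // real-space kernel tables over r in [tab_r0, rc]
  // mode 0: tabA = erfc(alpha r)/r
  // mode 1: tabA = B(r), tabB = C(r)
  std::vector<double> tabA, tabB;
  double tab_r0, tab_dr;
  int tab_n;

  // per-move phase-table scratch (allocated once)
  std::vector<cplx> exo, exn, eyo, eyn, ezo1, ezo2, ezn1, ezn2;

  // positions
  std::vector<double> x, y, z;

  double E;              // cached running energy
};

static double solve_alpha_x(double acc) {
  // x with erfc(x) ~ exp(-x^2)/(x sqrt(pi)) = acc
  double xv = 3.0;
  for (int it = 0; it < 40; ++it) {
    double t = -std::log(acc * xv * std::sqrt(PI_));
    if (t < 1.0) t = 1.0;
    xv = std::sqrt(t);
  }
  return xv;
}

static inline double kernA_direct(const EwaldCtx& C, double r) {
  if (C.mode == 0) return std::erfc(C.alpha * r) / r;
  double a = C.alpha;
  return std::erfc(a * r) / (r * r * r) +
         (2.0 * a / std::sqrt(PI_)) * std::exp(-a * a * r * r) / (r * r);
}
static inline double kernB_direct(const EwaldCtx& C, double r) {
  double a = C.alpha;
  double g = (2.0 * a / std::sqrt(PI_)) * std::exp(-a * a * r * r);
  return 3.0 * std::erfc(a * r) / (r * r * r * r * r) +
         g * (3.0 / (r * r * r * r) + 2.0 * a * a / (r * r));
}

static void build_tables(EwaldCtx& C) {
  C.tab_n = 65536;
  C.tab_r0 = 0.25 * C.R;
  C.tab_dr = (C.rc - C.tab_r0) / (C.tab_n - 1);
  C.tabA.resize(C.tab_n);
  if (C.mode == 1) C.tabB.resize(C.tab_n);
  for (int i = 0; i < C.tab_n; ++i) {
    double r = C.tab_r0 + i * C.tab_dr;
    C.tabA[i] = kernA_direct(C, r);
    if (C.mode == 1) C.tabB[i] = kernB_direct(C, r);
  }
}

static inline double kernA(const EwaldCtx& C, double r) {
  if (r < C.tab_r0) return kernA_direct(C, r);
  double u = (r - C.tab_r0) / C.tab_dr;
  int i = (int)u;
  if (i >= C.tab_n - 1) return kernA_direct(C, r);
  double f = u - i;
  return C.tabA[i] * (1.0 - f) + C.tabA[i + 1] * f;
}
static inline double kernB(const EwaldCtx& C, double r) {
  if (r < C.tab_r0) return kernB_direct(C, r);
  double u = (r - C.tab_r0) / C.tab_dr;
  int i = (int)u;
  if (i >= C.tab_n - 1) return kernB_direct(C, r);
  double f = u - i;
  return C.tabB[i] * (1.0 - f) + C.tabB[i + 1] * f;
}

static void build_S(EwaldCtx& C);

static void ctx_init(EwaldCtx& C, const NumericMatrix& centres,
                     const NumericVector& box, double R, double rho, double d,
                     double gamma, int mode, double accuracy,
                     double alpha_override) {
  C.N = centres.nrow();
  C.mode = mode;
  C.Lx = box[0]; C.Ly = box[1]; C.Lz = box[2];
  C.V = C.Lx * C.Ly * C.Lz;
  C.R = R; C.rho = rho; C.d = d;
  C.q2 = 2.0 * gamma * R;
  C.q = std::sqrt(C.q2);
  C.mu2 = 4.0 * C.q2 * d * d;
  C.live = (gamma > 0.0) && (d > 1e-12);

  C.x.resize(C.N); C.y.resize(C.N); C.z.resize(C.N);
  for (int i = 0; i < C.N; ++i) {
    C.x[i] = wrap0L(centres(i, 0), C.Lx);
    C.y[i] = wrap0L(centres(i, 1), C.Ly);
    C.z[i] = wrap0L(centres(i, 2), C.Lz);
  }
  if (!C.live) { C.E = 0.0; C.Econst = 0.0; return; }

  double Lmin = std::min(C.Lx, std::min(C.Ly, C.Lz));
  C.rc = 0.49999 * Lmin;
  double xv = solve_alpha_x(accuracy);
  C.alpha = std::isfinite(alpha_override) ? alpha_override : xv / C.rc;
  C.rc2 = C.rc * C.rc;
  double kmax = 2.0 * C.alpha * std::sqrt(-std::log(accuracy));
  // guard: never fewer than a couple of shells
  C.nmx = std::max(2, (int)std::ceil(kmax * C.Lx / (2.0 * PI_)));
  C.nmy = std::max(2, (int)std::ceil(kmax * C.Ly / (2.0 * PI_)));
  C.nmz = std::max(2, (int)std::ceil(kmax * C.Lz / (2.0 * PI_)));

  double k2max = kmax * kmax;
  double gx = 2.0 * PI_ / C.Lx, gy = 2.0 * PI_ / C.Ly, gz = 2.0 * PI_ / C.Lz;
  for (int nx = 0; nx <= C.nmx; ++nx)
    for (int ny = (nx == 0 ? 0 : -C.nmy); ny <= C.nmy; ++ny)
      for (int nz = ((nx == 0 && ny == 0) ? 1 : -C.nmz); nz <= C.nmz; ++nz) {
        double kx = gx * nx, ky = gy * ny, kz = gz * nz;
        double k2 = kx * kx + ky * ky + kz * kz;
        if (k2 > k2max) continue;
        double coef = 2.0 * (2.0 * PI_ / C.V) * std::exp(-k2 / (4.0 * C.alpha * C.alpha)) / k2;
        if (C.mode == 1) coef *= C.mu2 * kz * kz;
        C.inx.push_back(nx); C.iny.push_back(ny); C.inz.push_back(nz);
        C.kcoef.push_back(coef);
      }
  C.S.resize(C.kcoef.size());
  C.dS.resize(C.kcoef.size());
  C.exo.resize(C.nmx + 1); C.exn.resize(C.nmx + 1);
  C.eyo.resize(2 * C.nmy + 1); C.eyn.resize(2 * C.nmy + 1);
  C.ezo1.resize(2 * C.nmz + 1); C.ezo2.resize(2 * C.nmz + 1);
  C.ezn1.resize(2 * C.nmz + 1); C.ezn2.resize(2 * C.nmz + 1);

  build_tables(C);

  // configuration-independent terms: Gaussian self energy and (mode 0) the
  // intra-particle exclusion correction
  double Ec = 0.0;
  if (mode == 0) {
    Ec -= (C.alpha / std::sqrt(PI_)) * C.q2 * (2.0 * C.N);
    Ec += C.N * C.q2 * std::erf(2.0 * C.alpha * C.d) / (2.0 * C.d);
  } else {
    Ec -= (2.0 * std::pow(C.alpha, 3) / (3.0 * std::sqrt(PI_))) * C.mu2 * C.N;
  }
  C.Econst = Ec;
  build_S(C);
}

static void build_S(EwaldCtx& C) {
  size_t nk = C.kcoef.size();
  std::fill(C.S.begin(), C.S.end(), cplx(0.0, 0.0));
  double gx = 2.0 * PI_ / C.Lx, gy = 2.0 * PI_ / C.Ly, gz = 2.0 * PI_ / C.Lz;
  for (int p = 0; p < C.N; ++p) {
    // per-particle phase tables
    std::vector<cplx> ex(C.nmx + 1), ey(2 * C.nmy + 1), ezp(2 * C.nmz + 1), ezm(2 * C.nmz + 1);
    cplx fx(std::cos(gx * C.x[p]), std::sin(gx * C.x[p]));
    ex[0] = 1.0; for (int n = 1; n <= C.nmx; ++n) ex[n] = ex[n - 1] * fx;
    cplx fy(std::cos(gy * C.y[p]), std::sin(gy * C.y[p]));
    ey[C.nmy] = 1.0;
    for (int n = 1; n <= C.nmy; ++n) { ey[C.nmy + n] = ey[C.nmy + n - 1] * fy; ey[C.nmy - n] = std::conj(ey[C.nmy + n]); }
    if (C.mode == 0) {
      double zp = C.z[p] + C.d, zm = C.z[p] - C.d;
      cplx fzp(std::cos(gz * zp), std::sin(gz * zp)), fzm(std::cos(gz * zm), std::sin(gz * zm));
      ezp[C.nmz] = 1.0; ezm[C.nmz] = 1.0;
      for (int n = 1; n <= C.nmz; ++n) {
        ezp[C.nmz + n] = ezp[C.nmz + n - 1] * fzp; ezp[C.nmz - n] = std::conj(ezp[C.nmz + n]);
        ezm[C.nmz + n] = ezm[C.nmz + n - 1] * fzm; ezm[C.nmz - n] = std::conj(ezm[C.nmz + n]);
      }
      for (size_t k = 0; k < nk; ++k) {
        cplx pxy = ex[C.inx[k]] * ey[C.nmy + C.iny[k]];
        C.S[k] += C.q * pxy * (ezp[C.nmz + C.inz[k]] - ezm[C.nmz + C.inz[k]]);
      }
    } else {
      cplx fz(std::cos(gz * C.z[p]), std::sin(gz * C.z[p]));
      ezp[C.nmz] = 1.0;
      for (int n = 1; n <= C.nmz; ++n) { ezp[C.nmz + n] = ezp[C.nmz + n - 1] * fz; ezp[C.nmz - n] = std::conj(ezp[C.nmz + n]); }
      for (size_t k = 0; k < nk; ++k)
        C.S[k] += ex[C.inx[k]] * ey[C.nmy + C.iny[k]] * ezp[C.nmz + C.inz[k]];
    }
  }
}

// real-space energy between particles i and j (minimum image, cutoff rc)
static inline double real_pair(const EwaldCtx& C, int i, int j) {
  double dx = minimg(C.x[i] - C.x[j], C.Lx);
  double dy = minimg(C.y[i] - C.y[j], C.Ly);
  double dzc = C.z[i] - C.z[j];
  if (C.mode == 1) {
    double dz = minimg(dzc, C.Lz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > C.rc2) return 0.0;
    double r = std::sqrt(r2);
    return C.mu2 * (kernA(C, r) - kernB(C, r) * dz * dz);
  }
  double e = 0.0;
  for (int a = -1; a <= 1; a += 2)
    for (int b = -1; b <= 1; b += 2) {
      double dz = minimg(dzc + (a - b) * C.d, C.Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > C.rc2) continue;
      double r = std::sqrt(r2);
      e += (a * b) * C.q2 * kernA(C, r);
    }
  return e;
}

static double total_energy(EwaldCtx& C) {
  if (!C.live) return 0.0;
  double E = C.Econst;
  for (int i = 0; i < C.N; ++i)
    for (int j = i + 1; j < C.N; ++j)
      E += real_pair(C, i, j);
  for (size_t k = 0; k < C.kcoef.size(); ++k)
    E += C.kcoef[k] * std::norm(C.S[k]);
  return E;
}

// real-space energy of particle i at position (px,py,pz) with all others
static double real_one(const EwaldCtx& C, int i, double px, double py, double pz) {
  double e = 0.0;
  for (int j = 0; j < C.N; ++j) {
    if (j == i) continue;
    double dx = minimg(px - C.x[j], C.Lx);
    double dy = minimg(py - C.y[j], C.Ly);
    double dzc = pz - C.z[j];
    if (C.mode == 1) {
      double dz = minimg(dzc, C.Lz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > C.rc2) continue;
      double r = std::sqrt(r2);
      e += C.mu2 * (kernA(C, r) - kernB(C, r) * dz * dz);
    } else {
      for (int a = -1; a <= 1; a += 2)
        for (int b = -1; b <= 1; b += 2) {
          double dz = minimg(dzc + (a - b) * C.d, C.Lz);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > C.rc2) continue;
          double r = std::sqrt(r2);
          e += (a * b) * C.q2 * kernA(C, r);
        }
    }
  }
  return e;
}

// k-space + real-space energy change for moving particle i to (nxp,nyp,nzp);
// fills C.dS (call ctx_apply to commit)
static double move_delta(EwaldCtx& C, int i, double nxp, double nyp, double nzp) {
  if (!C.live) return 0.0;
  double dE = real_one(C, i, nxp, nyp, nzp) - real_one(C, i, C.x[i], C.y[i], C.z[i]);

  double gx = 2.0 * PI_ / C.Lx, gy = 2.0 * PI_ / C.Ly, gz = 2.0 * PI_ / C.Lz;
  // phase tables: old and new (scratch buffers owned by the context)
  std::vector<cplx> &exo = C.exo, &exn = C.exn, &eyo = C.eyo, &eyn = C.eyn,
                    &ezo1 = C.ezo1, &ezo2 = C.ezo2, &ezn1 = C.ezn1,
                    &ezn2 = C.ezn2;
  cplx f;
  f = cplx(std::cos(gx * C.x[i]), std::sin(gx * C.x[i]));
  exo[0] = 1.0; for (int n = 1; n <= C.nmx; ++n) exo[n] = exo[n - 1] * f;
  f = cplx(std::cos(gx * nxp), std::sin(gx * nxp));
  exn[0] = 1.0; for (int n = 1; n <= C.nmx; ++n) exn[n] = exn[n - 1] * f;
  f = cplx(std::cos(gy * C.y[i]), std::sin(gy * C.y[i]));
  eyo[C.nmy] = 1.0;
  for (int n = 1; n <= C.nmy; ++n) { eyo[C.nmy + n] = eyo[C.nmy + n - 1] * f; eyo[C.nmy - n] = std::conj(eyo[C.nmy + n]); }
  f = cplx(std::cos(gy * nyp), std::sin(gy * nyp));
  eyn[C.nmy] = 1.0;
  for (int n = 1; n <= C.nmy; ++n) { eyn[C.nmy + n] = eyn[C.nmy + n - 1] * f; eyn[C.nmy - n] = std::conj(eyn[C.nmy + n]); }

  double zo1 = (C.mode == 0) ? C.z[i] + C.d : C.z[i];
  double zo2 = C.z[i] - C.d;
  double zn1 = (C.mode == 0) ? nzp + C.d : nzp;
  double zn2 = nzp - C.d;
  f = cplx(std::cos(gz * zo1), std::sin(gz * zo1));
  ezo1[C.nmz] = 1.0;
  for (int n = 1; n <= C.nmz; ++n) { ezo1[C.nmz + n] = ezo1[C.nmz + n - 1] * f; ezo1[C.nmz - n] = std::conj(ezo1[C.nmz + n]); }
  f = cplx(std::cos(gz * zn1), std::sin(gz * zn1));
  ezn1[C.nmz] = 1.0;
  for (int n = 1; n <= C.nmz; ++n) { ezn1[C.nmz + n] = ezn1[C.nmz + n - 1] * f; ezn1[C.nmz - n] = std::conj(ezn1[C.nmz + n]); }
  if (C.mode == 0) {
    f = cplx(std::cos(gz * zo2), std::sin(gz * zo2));
    ezo2[C.nmz] = 1.0;
    for (int n = 1; n <= C.nmz; ++n) { ezo2[C.nmz + n] = ezo2[C.nmz + n - 1] * f; ezo2[C.nmz - n] = std::conj(ezo2[C.nmz + n]); }
    f = cplx(std::cos(gz * zn2), std::sin(gz * zn2));
    ezn2[C.nmz] = 1.0;
    for (int n = 1; n <= C.nmz; ++n) { ezn2[C.nmz + n] = ezn2[C.nmz + n - 1] * f; ezn2[C.nmz - n] = std::conj(ezn2[C.nmz + n]); }
  }

  size_t nk = C.kcoef.size();
  for (size_t k = 0; k < nk; ++k) {
    int ix = C.inx[k], iy = C.nmy + C.iny[k], iz = C.nmz + C.inz[k];
    cplx ds;
    if (C.mode == 0) {
      cplx zo = ezo1[iz] - ezo2[iz];
      cplx zn = ezn1[iz] - ezn2[iz];
      ds = C.q * (exn[ix] * eyn[iy] * zn - exo[ix] * eyo[iy] * zo);
    } else {
      ds = exn[ix] * eyn[iy] * ezn1[iz] - exo[ix] * eyo[iy] * ezo1[iz];
    }
    C.dS[k] = ds;
    dE += C.kcoef[k] * (2.0 * (C.S[k].real() * ds.real() + C.S[k].imag() * ds.imag()) + std::norm(ds));
  }
  return dE;
}

static void ctx_apply(EwaldCtx& C, int i, double nxp, double nyp, double nzp) {
  C.x[i] = nxp; C.y[i] = nyp; C.z[i] = nzp;
  if (!C.live) return;
  for (size_t k = 0; k < C.kcoef.size(); ++k) C.S[k] += C.dS[k];
}

// hard-core overlap of particle i at (px,py,pz) against all others
static bool any_overlap(const EwaldCtx& C, int i, double px, double py, double pz) {
  double sig2 = 4.0 * C.R * C.R;
  for (int j = 0; j < C.N; ++j) {
    if (j == i) continue;
    double dx = minimg(px - C.x[j], C.Lx);
    double dy = minimg(py - C.y[j], C.Ly);
    double dz = minimg(pz - C.z[j], C.Lz) / C.rho;
    if (dx * dx + dy * dy + dz * dz < sig2) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// Exported kernels
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_ewald_energy(NumericMatrix centres, NumericVector box, double R,
                        double rho, double d, double gamma, int mode,
                        double accuracy = 1e-5,
                        double alpha = NA_REAL) {
  EwaldCtx C;
  ctx_init(C, centres, box, R, rho, d, gamma, mode, accuracy, alpha);
  return total_energy(C);
}

// [[Rcpp::export]]
double cpp_ewald_delta(NumericMatrix centres, NumericVector box, double R,
                       double rho, double d, double gamma, int mode,
                       int i, NumericVector newpos, double accuracy = 1e-5) {
  EwaldCtx C;
  ctx_init(C, centres, box, R, rho, d, gamma, mode, accuracy, NA_REAL);
  double nx = wrap0L(newpos[0], C.Lx), ny = wrap0L(newpos[1], C.Ly),
         nz = wrap0L(newpos[2], C.Lz);
  return move_delta(C, i - 1, nx, ny, nz);
}

// [[Rcpp::export]]
double cpp_direct_energy(NumericMatrix centres, double R, double d,
                         double gamma, int mode) {
  int N = centres.nrow();
  double q2 = 2.0 * gamma * R;
  double mu2 = 4.0 * q2 * d * d;
  if (gamma <= 0.0 || (mode == 0 && d <= 1e-12)) return 0.0;
  double E = 0.0;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = centres(i, 0) - centres(j, 0);
      double dy = centres(i, 1) - centres(j, 1);
      double dzc = centres(i, 2) - centres(j, 2);
      double rxy2 = dx * dx + dy * dy;
      if (mode == 1) {
        double r2 = rxy2 + dzc * dzc;
        double r = std::sqrt(r2);
        E += mu2 * (1.0 - 3.0 * dzc * dzc / r2) / (r2 * r);
      } else {
        for (int a = -1; a <= 1; a += 2)
          for (int b = -1; b <= 1; b += 2) {
            double dz = dzc + (a - b) * d;
            double r = std::sqrt(rxy2 + dz * dz);
            E += (a * b) * q2 / r;
          }
      }
    }
  return E;
}

// Brute-force periodic oracle: cubic-shell image sum (vacuum boundary).
// Excludes intra-particle pairs in the primary cell only, like the Ewald sum.
// [[Rcpp::export]]
double cpp_image_shell_energy(NumericMatrix centres, NumericVector box,
                              double R, double d, double gamma, int nshell) {
  int N = centres.nrow();
  double q2 = 2.0 * gamma * R;
  if (gamma <= 0.0 || d <= 1e-12) return 0.0;
  int ns = 2 * N;
  std::vector<double> sx(ns), sy(ns), sz(ns), sq(ns);
  std::vector<int> pid(ns);
  double q = std::sqrt(q2);
  for (int i = 0; i < N; ++i) {
    sx[2 * i] = centres(i, 0); sy[2 * i] = centres(i, 1); sz[2 * i] = centres(i, 2) + d;
    sq[2 * i] = q; pid[2 * i] = i;
    sx[2 * i + 1] = centres(i, 0); sy[2 * i + 1] = centres(i, 1); sz[2 * i + 1] = centres(i, 2) - d;
    sq[2 * i + 1] = -q; pid[2 * i + 1] = i;
  }
  double E = 0.0;
  for (int cx = -nshell; cx <= nshell; ++cx)
    for (int cy = -nshell; cy <= nshell; ++cy)
      for (int cz = -nshell; cz <= nshell; ++cz) {
        bool home = (cx == 0 && cy == 0 && cz == 0);
        double ox = cx * box[0], oy = cy * box[1], oz = cz * box[2];
        for (int p = 0; p < ns; ++p)
          for (int r = 0; r < ns; ++r) {
            if (home && pid[p] == pid[r]) continue;
            double dx = sx[p] - sx[r] - ox;
            double dy = sy[p] - sy[r] - oy;
            double dz = sz[p] - sz[r] - oz;
            double rr = std::sqrt(dx * dx + dy * dy + dz * dz);
            E += 0.5 * sq[p] * sq[r] / rr;
          }
      }
  return E;
}

// [[Rcpp::export]]
NumericMatrix cpp_init_random(int n, NumericVector box, double R, double rho,
                              int seed, int max_attempts) {
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericMatrix out(n, 3);
  double sig2 = 4.0 * R * R;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts; ++att) {
      double px = U(rng) * box[0], py = U(rng) * box[1], pz = U(rng) * box[2];
      bool ok = true;
      for (int j = 0; j < i; ++j) {
        double dx = minimg(px - out(j, 0), box[0]);
        double dy = minimg(py - out(j, 1), box[1]);
        double dz = minimg(pz - out(j, 2), box[2]) / rho;
        if (dx * dx + dy * dy + dz * dz < sig2) { ok = false; break; }
      }
      if (ok) { out(i, 0) = px; out(i, 1) = py; out(i, 2) = pz; placed = true; break; }
    }
    if (!placed)
      stop("random insertion failed for particle %d of %d: volume fraction too "
           "high for sequential insertion; lower phi or n", i + 1, n);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix centres, NumericVector box, double R, double rho,
                double d, double gamma, int mode, int cycles, double disp,
                int seed, int stride, double accuracy = 1e-5,
                bool zero_temperature = false) {
  EwaldCtx C;
  ctx_init(C, centres, box, R, rho, d, gamma, mode, accuracy, NA_REAL);
  C.E = total_energy(C);

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  long attempted = 0, accepted = 0, overlap_rejected = 0;
  std::vector<int> snap_cycle;
  std::vector<double> snap_energy, snap_acc;
  List snaps;
  int rebuild_every = 5000;

  // initial frame
  {
    NumericMatrix m(C.N, 3);
    for (int p = 0; p < C.N; ++p) { m(p, 0) = C.x[p]; m(p, 1) = C.y[p]; m(p, 2) = C.z[p]; }
    snaps.push_back(m);
    snap_cycle.push_back(0); snap_energy.push_back(C.E); snap_acc.push_back(NA_REAL);
  }

  long acc_window = 0, att_window = 0;
  for (int cyc = 1; cyc <= cycles; ++cyc) {
    for (int mv = 0; mv < C.N; ++mv) {
      int i = (int)(U(rng) * C.N); if (i >= C.N) i = C.N - 1;
      double px = C.x[i] + disp * (2.0 * U(rng) - 1.0);
      double py = C.y[i] + disp * (2.0 * U(rng) - 1.0);
      double pz = C.z[i] + disp * (2.0 * U(rng) - 1.0);
      px = wrap0L(px, C.Lx); py = wrap0L(py, C.Ly); pz = wrap0L(pz, C.Lz);
      ++attempted; ++att_window;
      if (any_overlap(C, i, px, py, pz)) { ++overlap_rejected; continue; }
      double dE = C.live ? move_delta(C, i, px, py, pz) : 0.0;
      if (dE <= 0.0 || (!zero_temperature && U(rng) < std::exp(-dE))) {
        ctx_apply(C, i, px, py, pz);
        C.E += dE;
        ++accepted; ++acc_window;
      }
    }
    if (C.live && (cyc % rebuild_every == 0)) build_S(C);
    if (cyc % stride == 0 || cyc == cycles) {
      NumericMatrix m(C.N, 3);
      for (int p = 0; p < C.N; ++p) { m(p, 0) = C.x[p]; m(p, 1) = C.y[p]; m(p, 2) = C.z[p]; }
      snaps.push_back(m);
      snap_cycle.push_back(cyc);
      snap_energy.push_back(C.E);
      snap_acc.push_back(att_window > 0 ? (double)acc_window / att_window : NA_REAL);
      acc_window = 0; att_window = 0;
      if (cyc == cycles) break;  // avoid duplicate final frame
    }
  }

  double Efinal_recomputed = 0.0;
  if (C.live) {
    build_S(C);
    Efinal_recomputed = total_energy(C);
  }
  NumericMatrix fin(C.N, 3);
  for (int p = 0; p < C.N; ++p) { fin(p, 0) = C.x[p]; fin(p, 1) = C.y[p]; fin(p, 2) = C.z[p]; }

  return List::create(
    _["snapshots"] = snaps,
    _["cycle"] = snap_cycle,
    _["energy"] = snap_energy,
    _["acceptance"] = snap_acc,
    _["final_centres"] = fin,
    _["final_energy"] = C.E,
    _["final_energy_recomputed"] = Efinal_recomputed,
    _["attempted"] = (double)attempted,
    _["accepted"] = (double)accepted,
    _["overlap_rejected"] = (double)overlap_rejected);
}

// Periodic two-particle energy as a function of the displacement vector:
// particle 1 sits at the box centre, particle 2 at centre + delta (one row
// per evaluation). Used by the Boltzmann-distribution oracle in the tests.
// [[Rcpp::export]]
NumericVector cpp_pair_energy_map(NumericMatrix deltas, NumericVector box,
                                  double R, double rho, double d, double gamma,
                                  int mode, double accuracy = 1e-5) {
  NumericMatrix cen(2, 3);
  for (int k = 0; k < 3; ++k) { cen(0, k) = 0.5 * box[k]; cen(1, k) = 0.5 * box[k]; }
  EwaldCtx C;
  ctx_init(C, cen, box, R, rho, d, gamma, mode, accuracy, NA_REAL);
  NumericVector out(deltas.nrow());
  for (int r = 0; r < deltas.nrow(); ++r) {
    C.x[1] = wrap0L(0.5 * box[0] + deltas(r, 0), C.Lx);
    C.y[1] = wrap0L(0.5 * box[1] + deltas(r, 1), C.Ly);
    C.z[1] = wrap0L(0.5 * box[2] + deltas(r, 2), C.Lz);
    if (C.live) build_S(C);
    out[r] = total_energy(C);
  }
  return out;
}

// contact-function values for all pairs with F <= fmax; returns (i, j, F)
// with 1-based indices. box of length 0 means open (non-periodic) boundaries.
// [[Rcpp::export]]
NumericMatrix cpp_contact_edges(NumericMatrix centres, NumericVector box,
                                double R, double rho, double fmax) {
  int N = centres.nrow();
  bool periodic = box.size() == 3;
  std::vector<double> vi, vj, vf;
  double sig2 = 4.0 * R * R;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = centres(i, 0) - centres(j, 0);
      double dy = centres(i, 1) - centres(j, 1);
      double dz = centres(i, 2) - centres(j, 2);
      if (periodic) {
        dx = minimg(dx, box[0]); dy = minimg(dy, box[1]); dz = minimg(dz, box[2]);
      }
      dz /= rho;
      double F = (dx * dx + dy * dy + dz * dz) / sig2;
      if (F <= fmax) { vi.push_back(i + 1); vj.push_back(j + 1); vf.push_back(F); }
    }
  NumericMatrix out(vi.size(), 3);
  for (size_t r = 0; r < vi.size(); ++r) { out(r, 0) = vi[r]; out(r, 1) = vj[r]; out(r, 2) = vf[r]; }
  return out;
}

// [[Rcpp::export]]
bool cpp_any_overlap(NumericMatrix centres, NumericVector box, double R,
                     double rho, double tol = 0.0) {
  int N = centres.nrow();
  bool periodic = box.size() == 3;
  double sig2 = 4.0 * R * R * (1.0 - tol);
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx = centres(i, 0) - centres(j, 0);
      double dy = centres(i, 1) - centres(j, 1);
      double dz = centres(i, 2) - centres(j, 2);
      if (periodic) {
        dx = minimg(dx, box[0]); dy = minimg(dy, box[1]); dz = minimg(dz, box[2]);
      }
      dz /= rho;
      if (dx * dx + dy * dy + dz * dz < sig2) return true;
    }
  return false;
}
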