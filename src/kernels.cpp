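// Potential-energy kernels: analytic first derivatives with respect to both
// coordinates (forces) and every trainable parameter channel.  All units:
// nm, kJ/mol, e, radians.  The reverse pass through the integrator consumes
// these first derivatives; second-order terms are formed at the R level as
// directional finite differences of the values computed here.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KE = 138.935458;   // Coulomb constant, kJ mol^-1 nm e^-2
static const double EPS_SOLUTE = 1.0;
static const double EPS_SOLVENT = 78.5;
static const double NECK_SW_WIDTH = 0.01;  // nm, neck cutoff switch width

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

static inline Vec3 getv(const NumericMatrix& X, int i) {
  return Vec3(X(i, 0), X(i, 1), X(i, 2));
}
static inline void addf(NumericMatrix& F, int i, const Vec3& v) {
  F(i, 0) += v.x; F(i, 1) += v.y; F(i, 2) += v.z;
}

// ---------------------------------------------------------------- bonded --

static double bonded_terms(const NumericMatrix& X, const List& bonds,
                           const List& angles, const List& torsions,
                           int nbins, NumericMatrix& F, NumericVector& dk,
                           double& e_bond, double& e_angle, double& e_tor) {
  e_bond = e_angle = e_tor = 0.0;
  // harmonic bonds: E = k (r - r0)^2
  IntegerVector bi = bonds["i"], bj = bonds["j"];
  NumericVector bk = bonds["k"], br0 = bonds["r0"];
  for (int m = 0; m < bi.size(); ++m) {
    int i = bi[m] - 1, j = bj[m] - 1;
    Vec3 d = getv(X, i) - getv(X, j);
    double r = d.norm();
    double dr = r - br0[m];
    e_bond += bk[m] * dr * dr;
    double coef = -2.0 * bk[m] * dr / r;   // force on i along d
    addf(F, i, d * coef);
    addf(F, j, d * (-coef));
  }
  // harmonic angles: E = k (theta - theta0)^2
  IntegerVector ai = angles["i"], aj = angles["j"], ak = angles["k"];
  NumericVector akf = angles["kf"], ath = angles["theta0"];
  for (int m = 0; m < ai.size(); ++m) {
    int i = ai[m] - 1, j = aj[m] - 1, k = ak[m] - 1;
    Vec3 u = getv(X, i) - getv(X, j);
    Vec3 v = getv(X, k) - getv(X, j);
    double nu = u.norm(), nv = v.norm();
    double ct = u.dot(v) / (nu * nv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double th = std::acos(ct);
    double st = std::sqrt(std::max(1.0 - ct * ct, 1e-14));
    double dth = th - ath[m];
    e_angle += akf[m] * dth * dth;
    double dEdth = 2.0 * akf[m] * dth;
    Vec3 uh = u * (1.0 / nu), vh = v * (1.0 / nv);
    Vec3 dth_di = (uh * ct - vh) * (1.0 / (nu * st));
    Vec3 dth_dk = (vh * ct - uh) * (1.0 / (nv * st));
    addf(F, i, dth_di * (-dEdth));
    addf(F, k, dth_dk * (-dEdth));
    addf(F, j, (dth_di + dth_dk) * dEdth);
  }
  // periodic torsions: E = k (1 + cos(n phi - delta))
  IntegerVector ti = torsions["i"], tj = torsions["j"],
                tk = torsions["k"], tl = torsions["l"];
  NumericVector tn = torsions["n"], tkf = torsions["kf"],
                tph = torsions["phase"];
  IntegerVector tb = torsions["bin"];
  for (int m = 0; m < ti.size(); ++m) {
    int i = ti[m] - 1, j = tj[m] - 1, k = tk[m] - 1, l = tl[m] - 1;
    Vec3 b1 = getv(X, j) - getv(X, i);
    Vec3 b2 = getv(X, k) - getv(X, j);
    Vec3 b3 = getv(X, l) - getv(X, k);
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    double nb2 = b2.norm();
    double n1sq = n1.dot(n1), n2sq = n2.dot(n2);
    if (n1sq < 1e-14 || n2sq < 1e-14) continue;  // collinear; undefined
    Vec3 m1 = n1.cross(b2 * (1.0 / nb2));
    double phi = std::atan2(m1.dot(n2), n1.dot(n2));
    double arg = tn[m] * phi - tph[m];
    e_tor += tkf[m] * (1.0 + std::cos(arg));
    if (dk.size() > 0 && tb[m] >= 1)
      dk[tb[m] - 1] += 1.0 + std::cos(arg);
    double dEdphi = -tkf[m] * tn[m] * std::sin(arg);
    Vec3 dphi_di = n1 * (nb2 / n1sq);
    Vec3 dphi_dl = n2 * (-nb2 / n2sq);
    double p = b1.dot(b2) / (nb2 * nb2);
    double q = b3.dot(b2) / (nb2 * nb2);
    Vec3 dphi_dj = dphi_di * (-(p + 1.0)) + dphi_dl * q;
    Vec3 dphi_dk = dphi_di * p - dphi_dl * (q + 1.0);
    addf(F, i, dphi_di * (-dEdphi));
    addf(F, j, dphi_dj * (-dEdphi));
    addf(F, k, dphi_dk * (-dEdphi));
    addf(F, l, dphi_dl * (-dEdphi));
  }
  return e_bond + e_angle + e_tor;
}

// ------------------------------------------------------------ nonbonded --

static void nonbonded_terms(const NumericMatrix& X, const NumericVector& q,
                            const IntegerVector& type_idx,
                            const NumericVector& tsig,
                            const NumericVector& teps,
                            const IntegerMatrix& flag, double c14, double l14,
                            bool want_pgrad, NumericMatrix& F,
                            double& e_lj, double& e_coul,
                            NumericVector& dq, NumericVector& dsig,
                            NumericVector& deps, double& dc14, double& dl14) {
  int n = X.nrow();
  int nt = tsig.size();
  e_lj = e_coul = 0.0;
  // Lorentz-Berthelot combining tables per type pair
  std::vector<double> sig_c(nt * nt), isig_c(nt * nt), eps_c(nt * nt),
      ei_c(nt * nt), ej_c(nt * nt);
  for (int a = 0; a < nt; ++a)
    for (int b = 0; b < nt; ++b) {
      double sg = 0.5 * (tsig[a] + tsig[b]);
      double ep = std::sqrt(teps[a] * teps[b]);
      sig_c[a * nt + b] = sg;
      isig_c[a * nt + b] = sg > 0 ? 1.0 / sg : 0.0;
      eps_c[a * nt + b] = ep;
      ei_c[a * nt + b] = teps[a] > 0 ? ep / (2.0 * teps[a]) : 0.0;
      ej_c[a * nt + b] = teps[b] > 0 ? ep / (2.0 * teps[b]) : 0.0;
    }
  const double* px = &X(0, 0);
  const double* py = px + n;
  const double* pz = py + n;
  const int* pf = &flag(0, 0);
  for (int i = 0; i < n - 1; ++i) {
    double xi = px[i], yi = py[i], zi = pz[i];
    double qi = q[i];
    int ti = type_idx[i] - 1;
    for (int j = i + 1; j < n; ++j) {
      int fl = pf[i + (size_t)j * n];
      if (fl == 0) continue;
      double dx = xi - px[j], dy = yi - py[j], dz = zi - pz[j];
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r < 1e-9) stop("singular geometry: interacting pair at r = 0");
      double inv_r = 1.0 / r;
      double ljscale = (fl == 2) ? l14 : 1.0;
      double qscale = (fl == 2) ? c14 : 1.0;
      double dEdr = 0.0;
      int tc = ti * nt + (type_idx[j] - 1);
      double epsij = eps_c[tc];
      if (epsij > 0) {
        double srr = sig_c[tc] * inv_r;
        double sr2 = srr * srr;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        double e0 = 4.0 * epsij * (sr12 - sr6);
        e_lj += ljscale * e0;
        dEdr += ljscale * 4.0 * epsij * (-12.0 * sr12 + 6.0 * sr6) * inv_r;
        if (want_pgrad) {
          double de_dsig = ljscale * 4.0 * epsij *
            (12.0 * sr12 - 6.0 * sr6) * isig_c[tc];
          dsig[ti] += 0.5 * de_dsig;
          dsig[type_idx[j] - 1] += 0.5 * de_dsig;
          double de_depsij = ljscale * 4.0 * (sr12 - sr6);
          deps[ti] += de_depsij * ei_c[tc];
          deps[type_idx[j] - 1] += de_depsij * ej_c[tc];
          if (fl == 2) dl14 += e0;
        }
      }
      // Coulomb (vacuum; solvent screening lives in the GB term)
      double ec = KE * qi * q[j] * inv_r;
      e_coul += qscale * ec;
      dEdr += -qscale * ec * inv_r;
      if (want_pgrad) {
        dq[i] += qscale * KE * q[j] * inv_r;
        dq[j] += qscale * KE * qi * inv_r;
        if (fl == 2) dc14 += ec;
      }
      double coef = -dEdr * inv_r;
      F(i, 0) += coef * dx; F(i, 1) += coef * dy; F(i, 2) += coef * dz;
      F(j, 0) -= coef * dx; F(j, 1) -= coef * dy; F(j, 2) -= coef * dz;
    }
  }
}

// -------------------------------------------------------------------- GB --

// HCT descreening integral of atom i (reduced radius rt) by atom j's scaled
// sphere (radius sr) at separation r, with partial derivatives.
struct HctOut { double H, dr, dsr, drt; };

static HctOut hct_integral(double r, double inv_r, double rt, double sr) {
  HctOut o; o.H = o.dr = o.dsr = o.drt = 0.0;
  double U = r + sr;
  if (rt >= U) return o;
  double Lc = std::fabs(r - sr);
  bool Lrt = rt > Lc;
  double L = Lrt ? rt : Lc;
  double invL = 1.0 / L, invU = 1.0 / U;
  double invL2 = invL * invL, invU2 = invU * invU;
  double sri = sr * inv_r;
  double c2 = 0.25 * (r - sr * sri);
  double logLU = std::log(L * invU);
  double H = 0.5 * (invL - invU + c2 * (invU2 - invL2)
                    + 0.5 * logLU * inv_r);
  double dHdU = 0.5 * (invU2 - 2.0 * c2 * invU2 * invU
                       - 0.5 * inv_r * invU);
  double dHdL = 0.5 * (-invL2 + 2.0 * c2 * invL2 * invL
                       + 0.5 * inv_r * invL);
  double dHdr_e = 0.5 * (0.25 * (1.0 + sri * sri) * (invU2 - invL2)
                         - 0.5 * logLU * inv_r * inv_r);
  double dHdsr_e = 0.5 * (-0.5 * sri) * (invU2 - invL2);
  double sgn = (r > sr) ? 1.0 : -1.0;
  double dLdr = Lrt ? 0.0 : sgn;
  double dLdsr = Lrt ? 0.0 : -sgn;
  o.H = H;
  o.dr = dHdr_e + dHdU + dHdL * dLdr;
  o.dsr = dHdsr_e + dHdU + dHdL * dLdsr;
  o.drt = Lrt ? dHdL : 0.0;
  if (rt < sr - r) {             // atom i engulfed by the scaled sphere of j
    o.H += (1.0 / rt - invL);
    o.drt += -1.0 / (rt * rt);
    o.dr += invL2 * dLdr;          // d(-1/L)/dr
    o.dsr += invL2 * dLdsr;
    if (Lrt) o.drt += invL2;
  }
  return o;
}

// Smooth neck correction: position/height surrogate for the tabulated neck
// integral, with a logistic switch at r = rho_i + rho_j + neck_cutoff so the
// cutoff itself is differentiable.  Returns value and partials.
struct NeckOut { double K, dr, drho_i, drho_j, dpr, dnc, dns; };

static NeckOut neck_term(double r, double rho_i, double rho_j,
                         double inv_rho_i, double inv_rho_j,
                         double pr, double nc, double ns) {
  NeckOut o; o.K = o.dr = o.drho_i = o.drho_j = o.dpr = o.dnc = o.dns = 0.0;
  double swarg = (r - (rho_i + rho_j + nc)) / NECK_SW_WIDTH;
  if (swarg > 40.0) return o;
  double d0 = rho_i + rho_j + 1.6 * pr;
  double inv_d0 = 1.0 / d0;
  double m0 = 0.36 * pr * pr * inv_rho_i * inv_rho_j * inv_d0;
  // the lobe decays for r > d0 and plateaus at m0 below d0, keeping the
  // descreening sum (and hence the Born radii) monotone under approach
  double D = r > d0 ? r - d0 : 0.0;
  double D2 = D * D;
  double den = 1.0 + 100.0 * D2 + 3.0e5 * D2 * D2 * D2;
  double g = 1.0 / den;
  double gp = -g * g * (200.0 * D + 18.0e5 * D2 * D2 * D);  // dg/dD
  double sw = 1.0 / (1.0 + std::exp(swarg));
  double swp = -sw * (1.0 - sw) / NECK_SW_WIDTH;            // dsw/dr
  double m0_drho_i = -m0 * (inv_rho_i + inv_d0);
  double m0_drho_j = -m0 * (inv_rho_j + inv_d0);
  double m0_dpr = m0 * (2.0 / pr - 1.6 * inv_d0);
  o.K = ns * m0 * g * sw;
  o.dr = ns * m0 * (gp * sw + g * swp);
  o.drho_i = ns * (m0_drho_i * g * sw + m0 * gp * (-1.0) * sw
                   + m0 * g * (-swp));
  o.drho_j = ns * (m0_drho_j * g * sw + m0 * gp * (-1.0) * sw
                   + m0 * g * (-swp));
  o.dpr = ns * (m0_dpr * g * sw + m0 * gp * (-1.6) * sw);
  o.dnc = ns * m0 * g * (-swp);
  o.dns = m0 * g * sw;
  return o;
}

// Born radii for the current configuration (exported for the born_radii op).
// [[Rcpp::export]]
NumericVector cpp_born_radii(NumericMatrix X, NumericVector rho,
                             NumericVector S, NumericVector alpha,
                             NumericVector beta, NumericVector gamma,
                             NumericVector globals) {
  int n = X.nrow();
  double nc = globals[0], ns = globals[1], off = globals[2], pr = globals[3];
  NumericVector R(n);
  for (int i = 0; i < n; ++i) {
    double rt = rho[i] - off;
    if (rt <= 0) stop("non-positive reduced intrinsic radius");
    double I = 0.0;
    Vec3 xi = getv(X, i);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double r = (xi - getv(X, j)).norm();
      double inv_r = 1.0 / r;
      I += hct_integral(r, inv_r, rt, S[j] * (rho[j] - off)).H;
      I += neck_term(r, rho[i], rho[j], 1.0 / rho[i], 1.0 / rho[j],
                     pr, nc, ns).K;
    }
    double psi = I * rt;
    double Phi = alpha[i] * psi - beta[i] * psi * psi
               + gamma[i] * psi * psi * psi;
    double invR = 1.0 / rt - std::tanh(Phi) / rho[i];
    R[i] = 1.0 / invR;
  }
  return R;
}

static void gb_terms(const NumericMatrix& X, const NumericVector& q,
                     const NumericVector& rho, const NumericVector& S,
                     const NumericVector& alpha, const NumericVector& beta,
                     const NumericVector& gamma,
                     const IntegerVector& radius_class,
                     const IntegerVector& elem_class,
                     const NumericVector& globals, double kappa,
                     bool sa_on, bool want_pgrad,
                     NumericMatrix& F, double& e_polar, double& e_sa,
                     NumericVector& dq, NumericVector& d_radii,
                     NumericVector& d_obc, NumericVector& d_screen,
                     NumericVector& d_globals) {
  int n = X.nrow();
  double nc = globals[0], ns = globals[1], off = globals[2],
         pr = globals[3], saf = globals[4];
  std::vector<double> rt(n), I(n, 0.0), psi(n), Rb(n), th(n), inv_rho(n);
  for (int i = 0; i < n; ++i) {
    rt[i] = rho[i] - off;
    inv_rho[i] = 1.0 / rho[i];
    if (rt[i] <= 0) stop("non-positive reduced intrinsic radius");
  }
  // pass A: descreening sums over unordered pairs, caching pair derivatives
  // (the neck term is symmetric in i and j and is computed once per pair)
  int npair = n * (n - 1) / 2;
  std::vector<HctOut> hij(npair), hji(npair);
  std::vector<NeckOut> nkp(npair);
  std::vector<double> pr_r(npair);
  {
    int p_ = 0;
    for (int i = 0; i < n - 1; ++i) {
      Vec3 xi = getv(X, i);
      for (int j = i + 1; j < n; ++j, ++p_) {
        double r = (xi - getv(X, j)).norm();
        double inv_r = 1.0 / r;
        pr_r[p_] = r;
        hij[p_] = hct_integral(r, inv_r, rt[i], S[j] * rt[j]);
        hji[p_] = hct_integral(r, inv_r, rt[j], S[i] * rt[i]);
        nkp[p_] = neck_term(r, rho[i], rho[j], inv_rho[i], inv_rho[j],
                            pr, nc, ns);
        I[i] += hij[p_].H + nkp[p_].K;
        I[j] += hji[p_].H + nkp[p_].K;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    psi[i] = I[i] * rt[i];
    double p = psi[i];
    double Phi = alpha[i] * p - beta[i] * p * p + gamma[i] * p * p * p;
    th[i] = std::tanh(Phi);
    Rb[i] = 1.0 / (1.0 / rt[i] - th[i] / rho[i]);
  }
  // pass B: polar + surface energies, adjoint on born radii
  std::vector<double> aR(n, 0.0);
  e_polar = e_sa = 0.0;
  const double inv_ew = 1.0 / EPS_SOLVENT, inv_ep = 1.0 / EPS_SOLUTE;
  for (int i = 0; i < n; ++i) {
    Vec3 xi = getv(X, i);
    // diagonal (self) term, f = R_i
    double tau = inv_ep - std::exp(-kappa * Rb[i]) * inv_ew;
    e_polar += -0.5 * KE * tau * q[i] * q[i] / Rb[i];
    if (want_pgrad) dq[i] += -KE * tau * q[i] / Rb[i];
    double taup = kappa * std::exp(-kappa * Rb[i]) * inv_ew;
    aR[i] += -0.5 * KE * q[i] * q[i] * (taup / Rb[i] - tau / (Rb[i] * Rb[i]));
    for (int j = i + 1; j < n; ++j) {
      Vec3 d = xi - getv(X, j);
      double r2 = d.dot(d);
      double RiRj = Rb[i] * Rb[j];
      double ex = std::exp(-r2 / (4.0 * RiRj));
      double f = std::sqrt(r2 + RiRj * ex);
      double tauf = inv_ep - std::exp(-kappa * f) * inv_ew;
      double e = -KE * tauf * q[i] * q[j] / f;  // both orderings combined
      e_polar += e;
      if (want_pgrad) {
        dq[i] += -KE * tauf * q[j] / f;
        dq[j] += -KE * tauf * q[i] / f;
      }
      double taufp = kappa * std::exp(-kappa * f) * inv_ew;
      double dEdf = -KE * q[i] * q[j] * (taufp / f - tauf / (f * f));
      double r = std::sqrt(r2);
      double dfdr = (r > 1e-12) ? r * (1.0 - 0.25 * ex) / f : 0.0;
      double dfdRi = ex * (Rb[j] + r2 / (4.0 * Rb[i])) / (2.0 * f);
      double dfdRj = ex * (Rb[i] + r2 / (4.0 * Rb[j])) / (2.0 * f);
      aR[i] += dEdf * dfdRi;
      aR[j] += dEdf * dfdRj;
      if (r > 1e-12) {
        Vec3 fv = d * (-dEdf * dfdr / r);
        addf(F, i, fv);
        addf(F, j, fv * (-1.0));
      }
    }
    if (sa_on) {
      // ACE-style surface term on the degree of burial (rt/R)^6
      double rp = rho[i] + pr;
      double ratio = rt[i] / Rb[i];
      double r6 = std::pow(ratio, 6);
      double area = 4.0 * M_PI * rp * rp;
      e_sa += saf * area * r6;
      if (want_pgrad) {
        d_globals[4] += area * r6;                         // sa_factor
        d_globals[3] += saf * 8.0 * M_PI * rp * r6;        // probe radius
        int rc = radius_class[i] - 1;
        d_radii[rc] += saf * 8.0 * M_PI * rp * r6;         // rho direct
        // through rt = rho - offset
        double d_rt = saf * area * 6.0 * r6 / rt[i];
        d_radii[rc] += d_rt;
        d_globals[2] -= d_rt;
      }
      aR[i] += -saf * area * 6.0 * r6 / Rb[i];
    }
  }
  // per-atom chain: born radius -> psi -> descreening sum
  std::vector<double> apsi(n), art(n, 0.0), arho(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double R2 = Rb[i] * Rb[i];
    double sech2 = 1.0 - th[i] * th[i];
    double aPhi = aR[i] * R2 * sech2 / rho[i];
    double p = psi[i];
    if (want_pgrad) {
      int ec = elem_class[i] - 1;
      d_obc[3 * ec + 0] += aPhi * p;
      d_obc[3 * ec + 1] += -aPhi * p * p;
      d_obc[3 * ec + 2] += aPhi * p * p * p;
    }
    apsi[i] = aPhi * (alpha[i] - 2.0 * beta[i] * p + 3.0 * gamma[i] * p * p);
    art[i] += aR[i] * R2 / (rt[i] * rt[i]);      // direct 1/rt term
    arho[i] += -aR[i] * R2 * th[i] / (rho[i] * rho[i]);  // direct tanh/rho
    art[i] += apsi[i] * I[i];                    // psi = I * rt
  }
  // pass C: distribute descreening-sum adjoints using the cached pair
  // derivatives from pass A
  {
    int p_ = 0;
    for (int i = 0; i < n - 1; ++i) {
      Vec3 xi = getv(X, i);
      double aIi = apsi[i] * rt[i];
      for (int j = i + 1; j < n; ++j, ++p_) {
        double aIj = apsi[j] * rt[j];
        double aS = aIi + aIj;
        if (aIi == 0.0 && aIj == 0.0) continue;
        const HctOut& h1 = hij[p_];
        const HctOut& h2 = hji[p_];
        const NeckOut& nk = nkp[p_];
        double r = pr_r[p_];
        double dEdr = aIi * h1.dr + aIj * h2.dr + aS * nk.dr;
        if (r > 1e-12 && dEdr != 0.0) {
          Vec3 d = xi - getv(X, j);
          Vec3 fv = d * (-dEdr / r);
          addf(F, i, fv);
          addf(F, j, fv * (-1.0));
        }
        art[i] += aIi * h1.drt + aIj * h2.dsr * S[i];
        art[j] += aIj * h2.drt + aIi * h1.dsr * S[j];
        arho[i] += aS * nk.drho_i;
        arho[j] += aS * nk.drho_j;
        if (want_pgrad) {
          d_screen[elem_class[j] - 1] += aIi * h1.dsr * rt[j];
          d_screen[elem_class[i] - 1] += aIj * h2.dsr * rt[i];
          d_globals[3] += aS * nk.dpr;
          d_globals[0] += aS * nk.dnc;
          d_globals[1] += aS * nk.dns;
        }
      }
    }
  }
  if (want_pgrad) {
    for (int i = 0; i < n; ++i) {
      d_radii[radius_class[i] - 1] += art[i] + arho[i];
      d_globals[2] -= art[i];   // rt = rho - offset
    }
  }
}

// ------------------------------------------------------------ entry point --

// [[Rcpp::export]]
List cpp_eval_potential(NumericMatrix X, NumericVector q,
                        IntegerVector type_idx, NumericVector type_sigma,
                        NumericVector type_eps, IntegerMatrix pairflag,
                        List bonds, List angles, List torsions, int nbins,
                        NumericVector gb_rho, NumericVector gb_S,
                        NumericVector gb_alpha, NumericVector gb_beta,
                        NumericVector gb_gamma, IntegerVector radius_class,
                        IntegerVector elem_class, NumericVector gb_globals,
                        double kappa, double c14, double l14,
                        bool gb_on, bool sa_on, bool want_pgrad) {
  int n = X.nrow();
  NumericMatrix F(n, 3);
  double e_bond = 0, e_angle = 0, e_tor = 0, e_lj = 0, e_coul = 0,
         e_polar = 0, e_sa = 0;
  NumericVector dk(want_pgrad ? nbins : 0);
  bonded_terms(X, bonds, angles, torsions, nbins, F, dk,
               e_bond, e_angle, e_tor);
  int nt = type_sigma.size();
  NumericVector dq(want_pgrad ? n : 0), dsig(want_pgrad ? nt : 0),
                deps(want_pgrad ? nt : 0);
  double dc14 = 0, dl14 = 0;
  nonbonded_terms(X, q, type_idx, type_sigma, type_eps, pairflag, c14, l14,
                  want_pgrad, F, e_lj, e_coul, dq, dsig, deps, dc14, dl14);
  NumericVector d_radii(want_pgrad ? 6 : 0), d_obc(want_pgrad ? 12 : 0),
                d_screen(want_pgrad ? 4 : 0), d_globals(want_pgrad ? 5 : 0);
  if (gb_on)
    gb_terms(X, q, gb_rho, gb_S, gb_alpha, gb_beta, gb_gamma, radius_class,
             elem_class, gb_globals, kappa, sa_on, want_pgrad, F,
             e_polar, e_sa, dq, d_radii, d_obc, d_screen, d_globals);
  NumericVector energies = NumericVector::create(
      _["bond"] = e_bond, _["angle"] = e_angle, _["torsion"] = e_tor,
      _["lj"] = e_lj, _["coulomb"] = e_coul, _["gb_polar"] = e_polar,
      _["gb_surface"] = e_sa);
  List out = List::create(_["energies"] = energies, _["F"] = F);
  if (want_pgrad) {
    out["dq"] = dq; out["dsig"] = dsig; out["deps"] = deps;
    out["dk"] = dk; out["dc14"] = dc14; out["dl14"] = dl14;
    out["d_radii"] = d_radii; out["d_obc"] = d_obc;
    out["d_screen"] = d_screen; out["d_globals"] = d_globals;
  }
  return out;
}

// Round a numeric vector/matrix through IEEE single precision (used by the
// single-precision simulation mode).
// [[Rcpp::export]]
NumericVector cpp_round_float(NumericVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = (double)(float)x[i];
  out.attr("dim") = x.attr("dim");
  return out;
}
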