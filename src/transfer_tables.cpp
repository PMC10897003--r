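// Stationary and linear-response solutions of the Fokker-Planck equation of
// the exponential integrate-and-fire (EIF) neuron, via threshold integration
// (backward integration in voltage from the spike threshold with exponential
// stepping).  Produces the transfer surfaces
//   Phi_r(mu, sigma)  : stationary population rate (kHz)
//   Phi_V(mu, sigma)  : stationary mean membrane voltage (mV), refractory
//                       probability mass placed at the reset potential
//   Phi_tau(mu, sigma): effective timescale (ms) of the linear rate response
//                       to a modulation of the mean input, from a one-pole
//                       (exponential filter) fit at a single low frequency;
//                       the zero-frequency gain dr/dmu comes from a central
//                       finite difference of the stationary solver.
// Units: mV, ms; input mean mu in mV/ms, noise amplitude sigma in mV/sqrt(ms).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include "aln_interp.h"
using namespace Rcpp;

struct EifParams {
  double C, gL, EL, DeltaT, VT, Vs, Vr, Tref, taum;
};

static EifParams eif_from_list(const List& neuron) {
  EifParams p;
  p.C = as<double>(neuron["C"]);
  p.gL = as<double>(neuron["g_L"]);
  p.EL = as<double>(neuron["E_L"]);
  p.DeltaT = as<double>(neuron["Delta_T"]);
  p.VT = as<double>(neuron["V_T"]);
  p.Vs = as<double>(neuron["V_s"]);
  p.Vr = as<double>(neuron["V_reset"]);
  p.Tref = as<double>(neuron["T_ref"]);
  p.taum = p.C / p.gL;
  return p;
}

// Stationary threshold integration at one (mu, sigma).  q = p0/r solves
// dq/dV = (F q - H)/D downward from q(Vs) = 0, H the unit flux above reset.
// Rescaling keeps q representable across subthreshold barriers spanning
// hundreds of orders of magnitude.  Returns false on non-finite failure.
static bool steady_solve(const EifParams& p, double mu, double sigma,
                         const std::vector<double>& vgrid,
                         const std::vector<double>& fbase, double dV,
                         double* rate, double* vbar,
                         std::vector<double>* qstore, double* logscale_out) {
  const int n = (int)vgrid.size();
  const double D = 0.5 * sigma * sigma;
  const double RESCALE = 1e280, INV_RESCALE = 1e-280;
  const double LOG_RESCALE = std::log(RESCALE);

  double q = 0.0, I0 = 0.0, I1 = 0.0, logscale = 0.0;
  if (qstore) (*qstore)[n - 1] = 0.0;

  for (int k = n - 2; k >= 0; --k) {
    const double Vhi = vgrid[k + 1];
    const double F = 0.5 * (fbase[k] + fbase[k + 1]) + mu;
    const double H = (vgrid[k] >= p.Vr - 0.5 * dV) ? std::exp(-logscale) : 0.0;
    const double g = F * dV / D;
    double qn;
    if (std::fabs(g) > 1e-12) {
      qn = (q - H / F) * std::exp(-g) + H / F;
    } else {
      qn = q + H * dV / D;
    }
    if (qn < 0.0) qn = 0.0;  // guard tiny negative round-off
    I0 += 0.5 * (q + qn) * dV;
    I1 += 0.5 * (q * Vhi + qn * vgrid[k]) * dV;
    q = qn;
    if (q > RESCALE) {
      q *= INV_RESCALE;
      I0 *= INV_RESCALE;
      I1 *= INV_RESCALE;
      logscale += LOG_RESCALE;
    }
    if (qstore) (*qstore)[k] = q;
  }
  if (!std::isfinite(I0) || I0 < 0.0) return false;

  const double logI0 = (I0 > 0.0) ? std::log(I0) + logscale : -1e308;
  double r = (logI0 > 700.0) ? 0.0 : 1.0 / (p.Tref + std::exp(logI0));
  const double es = (logscale > 700.0) ? 0.0 : std::exp(-logscale);
  double vb = (I1 + p.Tref * p.Vr * es) / (I0 + p.Tref * es);
  if (!std::isfinite(r) || !std::isfinite(vb)) return false;
  *rate = r;
  *vbar = vb;
  if (logscale_out) *logscale_out = logscale;
  return true;
}

// One (mu, sigma) operating point.  Returns a status flag: 0 ok, 1 tau fell
// back to the membrane time constant (quiescent regime), 2 non-finite
// result (non-convergent integration).
static int solve_point(const EifParams& p, double mu, double sigma,
                       const std::vector<double>& vgrid,
                       const std::vector<double>& fbase, double dV,
                       double w_tau, double rate_floor, double* rate,
                       double* vbar, double* tau, std::vector<double>& qbuf) {
  const int n = (int)vgrid.size();
  const double D = 0.5 * sigma * sigma;
  double logscale = 0.0;
  if (!steady_solve(p, mu, sigma, vgrid, fbase, dV, rate, vbar, &qbuf,
                    &logscale))
    return 2;
  const double r = *rate;

  // Quiescent regime: vanishing response, fall back to the membrane time
  // constant (and skip the complex solve, whose dynamic range blows up).
  if (r < rate_floor || logscale > 0.0) {
    *tau = p.taum;
    return 1;
  }

  // zero-frequency gain dr/dmu by central finite difference
  const double dmu = 1e-3;
  double rp = 0, rm = 0, dum = 0;
  if (!steady_solve(p, mu + dmu, sigma, vgrid, fbase, dV, &rp, &dum, NULL,
                    NULL) ||
      !steady_solve(p, mu - dmu, sigma, vgrid, fbase, dV, &rm, &dum, NULL,
                    NULL))
    return 2;
  const double A0 = (rp - rm) / (2.0 * dmu);
  if (!(A0 > 0.0)) {
    *tau = p.taum;
    return 1;
  }

  // linear response at the probe frequency w_tau (rad/ms)
  const std::complex<double> iunit(0.0, 1.0);
  const double w = w_tau;
  const std::complex<double> reinj = std::exp(-iunit * (w * p.Tref));
  std::complex<double> jr(1.0, 0.0), pr(0.0, 0.0);
  std::complex<double> jE(0.0, 0.0), pE(0.0, 0.0);
  bool crossed = false;
  for (int k = n - 2; k >= 0; --k) {
    const double F = 0.5 * (fbase[k] + fbase[k + 1]) + mu;
    const double g = F * dV / D;
    const double p0 = r * qbuf[k + 1];
    if (!crossed && vgrid[k] < p.Vr - 0.5 * dV) {
      jr -= reinj;
      crossed = true;
    }
    std::complex<double> pr_new, pE_new;
    if (std::fabs(g) > 1e-12) {
      const double e = std::exp(-g);
      const std::complex<double> Ar = jr / F;
      const std::complex<double> AE = (jE + p0) / F;
      pr_new = (pr - Ar) * e + Ar;
      pE_new = (pE - AE) * e + AE;
    } else {
      pr_new = pr + jr * (dV / D);
      pE_new = pE + (jE + p0) * (dV / D);
    }
    jr -= iunit * (w * 0.5 * dV) * (pr + pr_new);
    jE -= iunit * (w * 0.5 * dV) * (pE + pE_new);
    pr = pr_new;
    pE = pE_new;
  }
  if (std::abs(jr) < 1e-300) return 2;
  const std::complex<double> Aw = -jE / jr;
  if (std::abs(Aw) < 1e-300) return 2;
  // one-pole fit A(w) = A0/(1 + i w tau)  =>  tau = Im(A0/A(w)) / w
  double tau_fit = (A0 / Aw).imag() / w;
  if (!std::isfinite(tau_fit)) return 2;
  if (tau_fit < 0.1) tau_fit = 0.1;  // floor: Phi_tau must stay positive
  *tau = tau_fit;
  return 0;
}

// [[Rcpp::export]]
List fp_transfer_tables_cpp(List neuron, NumericVector mu_grid,
                            NumericVector sigma_grid, double dV, double V_lb,
                            double w_tau, double rate_floor) {
  EifParams p = eif_from_list(neuron);
  const int nmu = mu_grid.size(), nsig = sigma_grid.size();
  const int n = (int)std::floor((p.Vs - V_lb) / dV) + 1;

  std::vector<double> vgrid(n), fbase(n);
  for (int k = 0; k < n; ++k) {
    double V = p.Vs - (n - 1 - k) * dV;
    vgrid[k] = V;
    fbase[k] = (-(V - p.EL) + p.DeltaT * std::exp((V - p.VT) / p.DeltaT)) / p.taum;
  }

  NumericMatrix r_tab(nmu, nsig), V_tab(nmu, nsig), tau_tab(nmu, nsig);
  IntegerMatrix flag(nmu, nsig);
  std::vector<double> qbuf(n);

  for (int j = 0; j < nsig; ++j) {
    for (int i = 0; i < nmu; ++i) {
      double r = 0, vb = 0, tau = 0;
      int fl = solve_point(p, mu_grid[i], sigma_grid[j], vgrid, fbase, dV,
                           w_tau, rate_floor, &r, &vb, &tau, qbuf);
      r_tab(i, j) = r;
      V_tab(i, j) = vb;
      tau_tab(i, j) = tau;
      flag(i, j) = fl;
    }
  }
  return List::create(_["r"] = r_tab, _["V"] = V_tab, _["tau"] = tau_tab,
                      _["flag"] = flag);
}

// [[Rcpp::export]]
List tables_lookup_cpp(NumericVector mu_grid, NumericVector sigma_grid,
                       NumericMatrix r_tab, NumericMatrix V_tab,
                       NumericMatrix tau_tab, NumericVector mu,
                       NumericVector sigma) {
  const int nq = mu.size();
  const int nx = mu_grid.size(), ny = sigma_grid.size();
  NumericVector r(nq), V(nq), tau(nq);
  for (int k = 0; k < nq; ++k) {
    if (!std::isfinite(mu[k]))
      stop("non-finite query for state variable 'mu'");
    if (!std::isfinite(sigma[k]))
      stop("non-finite query for state variable 'sigma'");
    int ix, iy;
    double fx, fy;
    bilinear_clamped(REAL(mu_grid), nx, REAL(sigma_grid), ny, mu[k], sigma[k],
                     &ix, &iy, &fx, &fy);
    r[k] = bilinear_value(REAL(r_tab), nx, ix, iy, fx, fy);
    V[k] = bilinear_value(REAL(V_tab), nx, ix, iy, fx, fy);
    tau[k] = bilinear_value(REAL(tau_tab), nx, ix, iy, fx, fy);
  }
  return List::create(_["rate"] = r, _["mean_voltage"] = V,
                      _["timescale"] = tau);
}
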