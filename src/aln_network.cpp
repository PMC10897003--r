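// Euler integration of the delay-coupled two-population ALN mean-field
// network.  Each node holds an excitatory (E) and an inhibitory (I)
// population; population rates, mean voltages and effective timescales come
// from precomputed Fokker-Planck transfer tables queried at the current
// (mean input, input noise amplitude).  Inter-regional coupling is
// exclusively E->E, weighted by the structural matrix C and delayed by D.
// Background noise is an independent Ornstein-Uhlenbeck process per
// population per region, each with its own deterministic stream seed.
// Units: mV, ms, kHz; currents as current/capacitance in mV/ms.

#include <Rcpp.h>
#include <vector>
#include "aln_rng.h"
#include "aln_interp.h"
using namespace Rcpp;

// [[Rcpp::export]]
List aln_simulate_cpp(NumericMatrix Cmat, IntegerMatrix Dsteps, List pop,
                      List glob, List tables, NumericVector stream_seeds,
                      int out_every) {
  const int n = Cmat.nrow();
  if (Dsteps.nrow() != n || Dsteps.ncol() != n || Cmat.ncol() != n)
    stop("connectome matrices must be square and of equal size");
  if (stream_seeds.size() != 2 * n)
    stop("need one stream seed per population per region (2n)");

  // population parameters
  const double JEE = as<double>(pop["J_EE"]), JIE = as<double>(pop["J_IE"]);
  const double JEI = as<double>(pop["J_EI"]), JII = as<double>(pop["J_II"]);
  const double cEE = as<double>(pop["c_EE"]), cIE = as<double>(pop["c_IE"]);
  const double cEI = as<double>(pop["c_EI"]), cII = as<double>(pop["c_II"]);
  const double tau_sE = as<double>(pop["tau_s_E"]);
  const double tau_sI = as<double>(pop["tau_s_I"]);
  const double KE = as<double>(pop["K_E"]), KI = as<double>(pop["K_I"]);
  const double dE = as<double>(pop["d_E"]), dI = as<double>(pop["d_I"]);
  const double sigma_ext = as<double>(pop["sigma_ext"]);
  const double muEext = as<double>(pop["mu_E_ext"]);
  const double muIext = as<double>(pop["mu_I_ext"]);
  const double alpha = as<double>(pop["alpha"]);
  const double beta = as<double>(pop["beta"]);
  const double tauA = as<double>(pop["tau_A"]);
  const double EA = as<double>(pop["E_A"]);
  const double Cap = as<double>(pop["C"]);
  const double taum = Cap / as<double>(pop["g_L"]);

  // global parameters
  const double Kgl = as<double>(glob["K_gl"]);
  const double sigma_ou = as<double>(glob["sigma_ou"]);
  const double tau_ou = as<double>(glob["tau_ou"]);
  const double dt = as<double>(glob["dt"]);
  const double duration_ms = as<double>(glob["duration"]) * 1000.0;
  const double transient_ms = as<double>(glob["transient"]) * 1000.0;

  // transfer tables
  NumericVector mu_grid = tables["mu_grid"];
  NumericVector sigma_grid = tables["sigma_grid"];
  NumericMatrix r_tab = tables["r_table"];
  NumericMatrix V_tab = tables["V_table"];
  NumericMatrix tau_tab = tables["tau_table"];
  const int ngx = mu_grid.size(), ngy = sigma_grid.size();
  const double* gx = REAL(mu_grid);
  const double* gy = REAL(sigma_grid);
  const double* rT = REAL(r_tab);
  const double* vT = REAL(V_tab);
  const double* tT = REAL(tau_tab);

  const int nsteps = (int)std::round(duration_ms / dt);
  const int ntrans = (int)std::round(transient_ms / dt);
  if (ntrans >= nsteps) stop("duration must exceed transient");
  int dE_steps = std::max(1, (int)std::round(dE / dt));
  int dI_steps = std::max(1, (int)std::round(dI / dt));

  int maxd = std::max(dE_steps, dI_steps);
  std::vector<int> dnet((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      int d = std::max(1, Dsteps(i, j));
      dnet[(size_t)i * n + j] = d;
      if (d > maxd) maxd = d;
    }
  int L = 1;
  while (L < maxd + 2) L <<= 1;
  const int mask = L - 1;

  // sparse row-wise edge lists over the non-zero couplings
  std::vector<int> row_ptr(n + 1, 0);
  std::vector<int> col_idx, edge_delay;
  std::vector<double> wgt, wgt2;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double c = Cmat(i, j);
      if (c != 0.0) {
        col_idx.push_back(j);
        edge_delay.push_back(dnet[(size_t)i * n + j]);
        wgt.push_back(c);
        wgt2.push_back(c * c);
      }
    }
    row_ptr[i + 1] = (int)col_idx.size();
  }

  // state
  std::vector<double> muE(n, muEext), muI(n, muIext);
  std::vector<double> ouE(n, 0.0), ouI(n, 0.0);
  std::vector<double> see(n, 0.0), sei(n, 0.0), sie(n, 0.0), sii(n, 0.0);
  std::vector<double> vee(n, 0.0), vei(n, 0.0), vie(n, 0.0), vii(n, 0.0);
  std::vector<double> IA(n, 0.0);
  std::vector<double> rEh((size_t)L * n, 0.0), rIh((size_t)L * n, 0.0);

  std::vector<AlnRng> rngE, rngI;
  rngE.reserve(n);
  rngI.reserve(n);
  for (int i = 0; i < n; ++i) {
    rngE.push_back(AlnRng((uint64_t)stream_seeds[2 * i]));
    rngI.push_back(AlnRng((uint64_t)stream_seeds[2 * i + 1]));
  }

  const double sqdt = std::sqrt(dt);
  const double sig_ext2 = sigma_ext * sigma_ext;
  // effective-input-rate prefactors: r_ab = c_ab * (K_b r_b + ...), the
  // dimensionless kHz*ms reading; the matching microscopic synapse jumps
  // its gate by (c_ab/tau_s,b)*(1-s) per presynaptic spike, i.e. a
  // single-spike PSC current amplitude of about c_ab (J_ab*c_ab/tau_s,b).
  // The synaptic current scale J_ab enters mu_syn and sigma_a only.
  const double aEE = cEE, aIE = cIE, aEI = cEI, aII = cII;
  const double bEE = aEE * aEE, bIE = aIE * aIE, bEI = aEI * aEI,
               bII = aII * aII;

  const int T_out = (nsteps - ntrans + out_every - 1) / out_every;
  NumericMatrix rate_E_out(n, T_out);
  NumericVector rate_I_mean(n);
  long long clamp_s = 0, clamp_v = 0;

  std::vector<double> rE_now(n), rI_now(n), sigE(n), sigI(n), VEbar(n),
      tauE(n), tauI(n);
  std::vector<double> ns1(n), ns2(n);

  for (int t = 0; t < nsteps; ++t) {
    // network E->E input: delayed rates weighted by C (mean) and C^2 (var)
    for (int i = 0; i < n; ++i) {
      double s1 = 0.0, s2 = 0.0;
      for (int e = row_ptr[i]; e < row_ptr[i + 1]; ++e) {
        const double r =
            rEh[(size_t)((t - edge_delay[e]) & mask) * n + col_idx[e]];
        s1 += wgt[e] * r;
        s2 += wgt2[e] * r;
      }
      ns1[i] = s1;
      ns2[i] = s2;
    }

    const int iE = ((t - dE_steps) & mask);
    const int iI = ((t - dI_steps) & mask);
    for (int i = 0; i < n; ++i) {
      const double rE_dE = rEh[(size_t)iE * n + i];
      const double rI_dE = rIh[(size_t)iE * n + i];
      const double rE_dI = rEh[(size_t)iI * n + i];
      const double rI_dI = rIh[(size_t)iI * n + i];

      // effective input rates (dimensionless) and their variances
      const double r_ee = aEE * (KE * rE_dE + Kgl * ns1[i]);
      const double rho_ee = bEE * (KE * rE_dE + Kgl * ns2[i]);
      const double r_ei = aEI * (KI * rI_dE);
      const double rho_ei = bEI * (KI * rI_dE);
      const double r_ie = aIE * (KE * rE_dI);
      const double rho_ie = bIE * (KE * rE_dI);
      const double r_ii = aII * (KI * rI_dI);
      const double rho_ii = bII * (KI * rI_dI);

      // membrane current variance from synaptic fluctuations
      const double s2e =
          2.0 * JEE * JEE * vee[i] * tau_sE * taum /
              ((1.0 + r_ee) * taum + tau_sE) +
          2.0 * JEI * JEI * vei[i] * tau_sI * taum /
              ((1.0 + r_ei) * taum + tau_sI) +
          sig_ext2;
      const double s2i =
          2.0 * JIE * JIE * vie[i] * tau_sE * taum /
              ((1.0 + r_ie) * taum + tau_sE) +
          2.0 * JII * JII * vii[i] * tau_sI * taum /
              ((1.0 + r_ii) * taum + tau_sI) +
          sig_ext2;
      sigE[i] = std::sqrt(s2e);
      sigI[i] = std::sqrt(s2i);

      // transfer-table lookups; adaptation shifts the E-population mean input
      const double muE_eff = muE[i] - IA[i] / Cap;
      if (!std::isfinite(muE_eff) || !std::isfinite(muI[i])) {
        stop("non-finite state at t = %f ms, node %d", t * dt, i + 1);
      }
      int ix, iy;
      double fx, fy;
      bilinear_clamped(gx, ngx, gy, ngy, muE_eff, sigE[i], &ix, &iy, &fx, &fy);
      rE_now[i] = bilinear_value(rT, ngx, ix, iy, fx, fy);
      VEbar[i] = bilinear_value(vT, ngx, ix, iy, fx, fy);
      tauE[i] = bilinear_value(tT, ngx, ix, iy, fx, fy);
      bilinear_clamped(gx, ngx, gy, ngy, muI[i], sigI[i], &ix, &iy, &fx, &fy);
      rI_now[i] = bilinear_value(rT, ngx, ix, iy, fx, fy);
      tauI[i] = bilinear_value(tT, ngx, ix, iy, fx, fy);

      // Euler updates
      const double dmuE =
          (JEE * see[i] + JEI * sei[i] + muEext + ouE[i] - muE[i]) / tauE[i];
      const double dmuI =
          (JIE * sie[i] + JII * sii[i] + muIext + ouI[i] - muI[i]) / tauI[i];
      // synaptic gate and gate-variance updates: the linear self-term is
      // taken implicitly (the subsystem's relaxation time tau_s/(1+r_ab)
      // can drop below dt during rate excursions; forward Euler would
      // overshoot [0,1] there, semi-implicit Euler preserves the bounds)
      const double hE = dt / tau_sE, hI = dt / tau_sI;
      double see_n = (see[i] + hE * r_ee) / (1.0 + hE * (1.0 + r_ee));
      double sei_n = (sei[i] + hI * r_ei) / (1.0 + hI * (1.0 + r_ei));
      double sie_n = (sie[i] + hE * r_ie) / (1.0 + hE * (1.0 + r_ie));
      double sii_n = (sii[i] + hI * r_ii) / (1.0 + hI * (1.0 + r_ii));
      const double hE2 = dt / (tau_sE * tau_sE), hI2 = dt / (tau_sI * tau_sI);
      double om = 1.0 - see[i];
      double vee_n = (vee[i] + hE2 * om * om * rho_ee) /
                     (1.0 + hE2 * (2.0 * tau_sE * (r_ee + 1.0) - rho_ee));
      om = 1.0 - sei[i];
      double vei_n = (vei[i] + hI2 * om * om * rho_ei) /
                     (1.0 + hI2 * (2.0 * tau_sI * (r_ei + 1.0) - rho_ei));
      om = 1.0 - sie[i];
      double vie_n = (vie[i] + hE2 * om * om * rho_ie) /
                     (1.0 + hE2 * (2.0 * tau_sE * (r_ie + 1.0) - rho_ie));
      om = 1.0 - sii[i];
      double vii_n = (vii[i] + hI2 * om * om * rho_ii) /
                     (1.0 + hI2 * (2.0 * tau_sI * (r_ii + 1.0) - rho_ii));
      if (see_n < 0.0 || see_n > 1.0 || sei_n < 0.0 || sei_n > 1.0 ||
          sie_n < 0.0 || sie_n > 1.0 || sii_n < 0.0 || sii_n > 1.0) {
        ++clamp_s;
        see_n = std::min(1.0, std::max(0.0, see_n));
        sei_n = std::min(1.0, std::max(0.0, sei_n));
        sie_n = std::min(1.0, std::max(0.0, sie_n));
        sii_n = std::min(1.0, std::max(0.0, sii_n));
      }
      if (vee_n < 0.0 || vei_n < 0.0 || vie_n < 0.0 || vii_n < 0.0) {
        ++clamp_v;
        vee_n = std::max(0.0, vee_n);
        vei_n = std::max(0.0, vei_n);
        vie_n = std::max(0.0, vie_n);
        vii_n = std::max(0.0, vii_n);
      }
      muE[i] += dt * dmuE;
      muI[i] += dt * dmuI;
      see[i] = see_n; sei[i] = sei_n; sie[i] = sie_n; sii[i] = sii_n;
      vee[i] = vee_n; vei[i] = vei_n; vie[i] = vie_n; vii[i] = vii_n;
      IA[i] += dt * ((alpha * (VEbar[i] - EA) - IA[i]) / tauA +
                     beta * rE_now[i]);

      // Ornstein-Uhlenbeck background noise (Euler-Maruyama)
      ouE[i] += dt * (-ouE[i] / tau_ou);
      ouI[i] += dt * (-ouI[i] / tau_ou);
      if (sigma_ou > 0.0) {
        ouE[i] += sigma_ou * sqdt * rngE[i].rnorm();
        ouI[i] += sigma_ou * sqdt * rngI[i].rnorm();
      }
    }

    // push rates into the delay history at slot t
    double* slotE = &rEh[(size_t)(t & mask) * n];
    double* slotI = &rIh[(size_t)(t & mask) * n];
    for (int i = 0; i < n; ++i) {
      slotE[i] = rE_now[i];
      slotI[i] = rI_now[i];
    }

    if (t >= ntrans) {
      const int k = t - ntrans;
      if (k % out_every == 0) {
        const int col = k / out_every;
        for (int i = 0; i < n; ++i) rate_E_out(i, col) = rE_now[i];
      }
      for (int i = 0; i < n; ++i) rate_I_mean[i] += rI_now[i];
    }
  }

  const double nmeas = (double)(nsteps - ntrans);
  for (int i = 0; i < n; ++i) rate_I_mean[i] /= nmeas;

  return List::create(_["rate_E"] = rate_E_out,
                      _["rate_I_mean"] = rate_I_mean,
                      _["clamp_events_s"] = (double)clamp_s,
                      _["clamp_events_var"] = (double)clamp_v,
                      _["n_steps"] = nsteps, _["n_transient"] = ntrans);
}
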