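// Monte-Carlo spiking-network oracles.
//
// eif_mc_rate_cpp: ensemble of uncoupled exponential integrate-and-fire
// neurons driven by white noise of given mean/amplitude (Euler-Maruyama);
// independent reference for the Fokker-Planck transfer tables.
//
// adex_net_rate_cpp: recurrent network of AdEx neurons (one excitatory and
// one inhibitory population, fixed in-degrees, saturating single-exponential
// synaptic gates, per-target-population synaptic delays, somatic adaptation
// on the excitatory population).  Its mean-field reduction is the ALN node,
// so it serves as the independent reference for the node's stationary rate.
//
// Units: mV, ms, kHz; currents as current/capacitance in mV/ms.

#include <Rcpp.h>
#include <vector>
#include "aln_rng.h"
using namespace Rcpp;

// [[Rcpp::export]]
List eif_mc_rate_cpp(List neuron, double mu, double sigma, int n_neurons,
                     double T_ms, double dt, double transient_ms, int seed) {
  const double C = as<double>(neuron["C"]);
  const double gL = as<double>(neuron["g_L"]);
  const double EL = as<double>(neuron["E_L"]);
  const double DeltaT = as<double>(neuron["Delta_T"]);
  const double VT = as<double>(neuron["V_T"]);
  const double Vs = as<double>(neuron["V_s"]);
  const double Vr = as<double>(neuron["V_reset"]);
  const double Tref = as<double>(neuron["T_ref"]);
  const double taum = C / gL;

  const int nsteps = (int)std::round(T_ms / dt);
  const int ntrans = (int)std::round(transient_ms / dt);
  const int ref_steps = (int)std::round(Tref / dt);
  const double sqdt = std::sqrt(dt);

  AlnRng rng((uint64_t)seed * 2654435761ULL + 7ULL);
  std::vector<double> V(n_neurons, EL);
  std::vector<int> ref(n_neurons, 0);
  // de-synchronised start: V uniform in [Vr, VT]
  for (int i = 0; i < n_neurons; ++i)
    V[i] = Vr + (VT - Vr) * rng.runif_pos();

  long long spikes = 0;
  for (int t = 0; t < nsteps; ++t) {
    const bool count = (t >= ntrans);
    for (int i = 0; i < n_neurons; ++i) {
      if (ref[i] > 0) {
        --ref[i];
        continue;
      }
      const double v = V[i];
      const double drift =
          (-(v - EL) + DeltaT * std::exp((v - VT) / DeltaT)) / taum + mu;
      double vn = v + dt * drift + sigma * sqdt * rng.rnorm();
      if (vn >= Vs) {
        if (count) ++spikes;
        vn = Vr;
        ref[i] = ref_steps;
      }
      V[i] = vn;
    }
  }
  const double T_measured = (nsteps - ntrans) * dt;  // ms
  const double rate = (double)spikes / ((double)n_neurons * T_measured); // kHz
  return List::create(_["rate"] = rate, _["n_spikes"] = (double)spikes,
                      _["T_measured_ms"] = T_measured);
}

// [[Rcpp::export]]
List adex_net_rate_cpp(List neuron, List pop, double mu_e_ext,
                       double mu_i_ext, int NE, int NI, double T_ms,
                       double dt, double transient_ms, int seed) {
  const double C = as<double>(neuron["C"]);
  const double gL = as<double>(neuron["g_L"]);
  const double EL = as<double>(neuron["E_L"]);
  const double DeltaT = as<double>(neuron["Delta_T"]);
  const double VT = as<double>(neuron["V_T"]);
  const double Vs = as<double>(neuron["V_s"]);
  const double Vr = as<double>(neuron["V_reset"]);
  const double Tref = as<double>(neuron["T_ref"]);
  const double taum = C / gL;

  const double JEE = as<double>(pop["J_EE"]), JIE = as<double>(pop["J_IE"]);
  const double JEI = as<double>(pop["J_EI"]), JII = as<double>(pop["J_II"]);
  const double cEE = as<double>(pop["c_EE"]), cIE = as<double>(pop["c_IE"]);
  const double cEI = as<double>(pop["c_EI"]), cII = as<double>(pop["c_II"]);
  const double tau_sE = as<double>(pop["tau_s_E"]);
  const double tau_sI = as<double>(pop["tau_s_I"]);
  const int KE = (int)as<double>(pop["K_E"]);
  const int KI = (int)as<double>(pop["K_I"]);
  const double dE = as<double>(pop["d_E"]), dI = as<double>(pop["d_I"]);
  const double sigma_ext = as<double>(pop["sigma_ext"]);
  const double alpha = as<double>(pop["alpha"]);
  const double beta = as<double>(pop["beta"]);
  const double tauA = as<double>(pop["tau_A"]);
  const double EA = as<double>(pop["E_A"]);

  const int N = NE + NI;
  const int nsteps = (int)std::round(T_ms / dt);
  const int ntrans = (int)std::round(transient_ms / dt);
  const int ref_steps = (int)std::round(Tref / dt);
  const int dE_steps = (int)std::round(dE / dt);
  const int dI_steps = (int)std::round(dI / dt);
  const int ring = std::max(dE_steps, dI_steps) + 1;
  const double sqdt = std::sqrt(dt);
  // per-spike saturating gate increments c_ab/tau_s,b: the jump matching
  // the mean-field effective input rate r_ab = c_ab*(K_b r_b + ...); the
  // resulting single-spike PSC current amplitude is J_ab*c_ab/tau_s,b,
  // of the order of the nominal amplitude c_ab
  const double jmpEE = cEE / tau_sE;  // E source -> E target gate sE
  const double jmpIE = cIE / tau_sE;  // E source -> I target gate sE
  const double jmpEI = cEI / tau_sI;  // I source -> E target gate sI
  const double jmpII = cII / tau_sI;  // I source -> I target gate sI
  const double decE = dt / tau_sE, decI = dt / tau_sI;

  AlnRng rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 13ULL);

  // fixed in-degree connectivity, stored as out-adjacency for delivery
  std::vector<std::vector<int> > outE(NE), outI(NI);
  for (int tgt = 0; tgt < N; ++tgt) {
    for (int k = 0; k < KE; ++k)
      outE[(int)(rng.next() % (uint64_t)NE)].push_back(tgt);
    for (int k = 0; k < KI; ++k)
      outI[(int)(rng.next() % (uint64_t)NI)].push_back(tgt);
  }

  std::vector<double> V(N), sE(N, 0.0), sI(N, 0.0), w(NE, 0.0);
  std::vector<int> ref(N, 0);
  for (int i = 0; i < N; ++i) V[i] = Vr + (VT - Vr) * rng.runif_pos();

  // ring buffer of spike lists per step (sources, E and I separately)
  std::vector<std::vector<int> > spkE(ring), spkI(ring);

  long long e_spikes = 0, i_spikes = 0;
  double acc_sE_E = 0, acc_sI_E = 0, acc_w = 0, acc_V = 0;
  long long acc_n = 0;
  for (int t = 0; t < nsteps; ++t) {
    const bool count = (t >= ntrans);
    // deliver spikes due now
    {
      std::vector<int>& dueE_E = spkE[(t + ring - dE_steps) % ring];
      for (size_t m = 0; m < dueE_E.size(); ++m) {
        const std::vector<int>& tg = outE[dueE_E[m]];
        for (size_t a = 0; a < tg.size(); ++a) {
          int i = tg[a];
          if (i < NE) sE[i] += jmpEE * (1.0 - sE[i]);
        }
      }
      std::vector<int>& dueE_I = spkE[(t + ring - dI_steps) % ring];
      for (size_t m = 0; m < dueE_I.size(); ++m) {
        const std::vector<int>& tg = outE[dueE_I[m]];
        for (size_t a = 0; a < tg.size(); ++a) {
          int i = tg[a];
          if (i >= NE) sE[i] += jmpIE * (1.0 - sE[i]);
        }
      }
      std::vector<int>& dueI_E = spkI[(t + ring - dE_steps) % ring];
      for (size_t m = 0; m < dueI_E.size(); ++m) {
        const std::vector<int>& tg = outI[dueI_E[m]];
        for (size_t a = 0; a < tg.size(); ++a) {
          int i = tg[a];
          if (i < NE) sI[i] += jmpEI * (1.0 - sI[i]);
        }
      }
      std::vector<int>& dueI_I = spkI[(t + ring - dI_steps) % ring];
      for (size_t m = 0; m < dueI_I.size(); ++m) {
        const std::vector<int>& tg = outI[dueI_I[m]];
        for (size_t a = 0; a < tg.size(); ++a) {
          int i = tg[a];
          if (i >= NE) sI[i] += jmpII * (1.0 - sI[i]);
        }
      }
    }
    // clear the slot spikes emitted this step will occupy
    std::vector<int>& slotE = spkE[t % ring];
    std::vector<int>& slotI = spkI[t % ring];
    slotE.clear();
    slotI.clear();

    if (count && t % 100 == 0) {
      for (int i = 0; i < NE; ++i) {
        acc_sE_E += sE[i];
        acc_sI_E += sI[i];
        acc_w += w[i];
        acc_V += V[i];
      }
      acc_n += NE;
    }
    for (int i = 0; i < N; ++i) {
      const bool isE = (i < NE);
      // gates decay regardless of refractory state
      sE[i] -= decE * sE[i];
      sI[i] -= decI * sI[i];
      if (isE) w[i] += dt * ((alpha * (V[i] - EA) - w[i]) / tauA);
      if (ref[i] > 0) {
        --ref[i];
        continue;
      }
      const double v = V[i];
      double drive = (isE ? JEE : JIE) * sE[i] + (isE ? JEI : JII) * sI[i] +
                     (isE ? mu_e_ext : mu_i_ext);
      if (isE) drive -= w[i] / C;
      const double drift =
          (-(v - EL) + DeltaT * std::exp((v - VT) / DeltaT)) / taum + drive;
      double vn = v + dt * drift + sigma_ext * sqdt * rng.rnorm();
      if (vn >= Vs) {
        vn = Vr;
        ref[i] = ref_steps;
        if (isE) {
          w[i] += beta;
          slotE.push_back(i);
          if (count) ++e_spikes;
        } else {
          slotI.push_back(i - NE);
          if (count) ++i_spikes;
        }
      }
      V[i] = vn;
    }
  }
  const double T_measured = (nsteps - ntrans) * dt;
  const double rate_E = (double)e_spikes / ((double)NE * T_measured);  // kHz
  const double rate_I = (double)i_spikes / ((double)NI * T_measured);  // kHz
  return List::create(_["rate_E"] = rate_E, _["rate_I"] = rate_I,
                      _["n_spikes_E"] = (double)e_spikes,
                      _["mean_s_EE"] = acc_sE_E / acc_n,
                      _["mean_s_EI"] = acc_sI_E / acc_n,
                      _["mean_w_pA"] = acc_w / acc_n,
                      _["mean_V_E"] = acc_V / acc_n,
                      _["T_measured_ms"] = T_measured);
}
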