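#' AdEx/EIF single-neuron parameters
#'
#' Parameters of the exponential integrate-and-fire neuron underlying the
#' population transfer functions.  Defaults are the network's reference
#' values; the membrane time constant `tau_m = C / g_L` is derived, never
#' set directly.
#'
#' @param C Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param E_L Leak reversal potential (mV).
#' @param Delta_T Threshold slope factor (mV).
#' @param V_T Threshold voltage (mV).
#' @param V_s Spike voltage threshold (mV); integration treats this as the
#'   absorbing spike boundary.
#' @param V_reset Reset voltage after a spike (mV).
#' @param T_ref Refractory time (ms).
#'
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(C = 200, g_L = 10, E_L = -65, Delta_T = 1.5,
                          V_T = -50, V_s = -40, V_reset = -70, T_ref = 1.5) {
  stopifnot(C > 0, g_L > 0, Delta_T > 0, T_ref >= 0)
  if (V_s <= V_T) {
    stop("spike threshold V_s must exceed the soft threshold V_T")
  }
  p <- list(C = C, g_L = g_L, E_L = E_L, Delta_T = Delta_T, V_T = V_T,
            V_s = V_s, V_reset = V_reset, T_ref = T_ref, tau_m = C / g_L)
  class(p) <- "neuron_params"
  p
}

#' Two-population (E/I) node parameters
#'
#' Synaptic, input and adaptation parameters of one ALN node.  Inhibitory
#' maximum synaptic currents are negative by convention.  Defaults are the
#' whole-brain model's reference values.
#'
#' @param J_EE,J_IE,J_EI,J_II Maximum synaptic currents (mV/ms); `J_EI`,
#'   `J_II` must be negative, `J_EE`, `J_IE` positive.
#' @param c_EE,c_IE,c_EI,c_II Single-spike post-synaptic amplitudes; these
#'   act as the per-spike increments of the saturating synaptic gates.
#' @param tau_s_E,tau_s_I Synaptic time constants (ms).
#' @param K_E,K_I Numbers of excitatory/inhibitory inputs per neuron.
#' @param d_E,d_I Local synaptic delays (ms) onto the E and I population.
#' @param sigma_ext Standard deviation of the external white-noise input
#'   (mV/sqrt(ms)).
#' @param mu_E_ext,mu_I_ext Mean external input currents (mV/ms).
#' @param alpha Subthreshold adaptation conductance (nS).
#' @param beta Spike-triggered adaptation increment (pA).
#' @param tau_A Adaptation time constant (ms).
#' @param E_A Adaptation reversal potential (mV).
#' @param C,g_L Membrane capacitance (pF) and leak conductance (nS); must
#'   match the neuron parameters used to build the transfer tables.
#'
#' @return An object of class `population_params`.
#' @export
population_params <- function(J_EE = 2.4, J_IE = 2.6, J_EI = -3.3,
                              J_II = -1.6, c_EE = 0.3, c_IE = 0.3,
                              c_EI = 0.5, c_II = 0.5, tau_s_E = 2,
                              tau_s_I = 5, K_E = 800, K_I = 200, d_E = 4,
                              d_I = 2, sigma_ext = 1.5, mu_E_ext = 1.63,
                              mu_I_ext = 0.05, alpha = 28.26, beta = 24.04,
                              tau_A = 200, E_A = -80, C = 200, g_L = 10) {
  stopifnot(tau_s_E > 0, tau_s_I > 0, K_E > 0, K_I > 0, tau_A > 0,
            d_E >= 0, d_I >= 0, sigma_ext >= 0, C > 0, g_L > 0)
  if (!(J_EI < 0 && J_II < 0)) {
    stop("inhibitory synaptic currents J_EI and J_II must be negative")
  }
  if (!(J_EE > 0 && J_IE > 0)) {
    stop("excitatory synaptic currents J_EE and J_IE must be positive")
  }
  p <- list(J_EE = J_EE, J_IE = J_IE, J_EI = J_EI, J_II = J_II, c_EE = c_EE,
            c_IE = c_IE, c_EI = c_EI, c_II = c_II, tau_s_E = tau_s_E,
            tau_s_I = tau_s_I, K_E = K_E, K_I = K_I, d_E = d_E, d_I = d_I,
            sigma_ext = sigma_ext, mu_E_ext = mu_E_ext, mu_I_ext = mu_I_ext,
            alpha = alpha, beta = beta, tau_A = tau_A, E_A = E_A, C = C,
            g_L = g_L)
  class(p) <- "population_params"
  p
}

#' Global network and integration parameters
#'
#' @param K_gl Global coupling strength (dimensionless multiplier of the
#'   inter-regional E-to-E input).
#' @param v_gl Global signal speed (m/s), converting fibre lengths to delays.
#' @param sigma_ou Ornstein-Uhlenbeck fluctuation amplitude (mV ms^(-3/2)).
#' @param tau_ou Ornstein-Uhlenbeck time constant (ms).
#' @param dt Integration step (ms).
#' @param duration Total simulated time (s).
#' @param transient Initial span discarded before analysis (s).
#'
#' @return An object of class `global_params`.
#' @export
global_params <- function(K_gl = 250, v_gl = 20, sigma_ou = 0.19,
                          tau_ou = 5, dt = 0.1, duration = 70,
                          transient = 5) {
  stopifnot(dt > 0, tau_ou > 0, sigma_ou >= 0, v_gl > 0, K_gl >= 0)
  if (!(duration > transient && transient >= 0)) {
    stop("'duration' must exceed 'transient' (and transient must be >= 0)")
  }
  p <- list(K_gl = K_gl, v_gl = v_gl, sigma_ou = sigma_ou, tau_ou = tau_ou,
            dt = dt, duration = duration, transient = transient)
  class(p) <- "global_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("EIF/AdEx neuron parameters (tau_m =", x$tau_m, "ms)\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @importFrom utils str
#' @export
print.population_params <- function(x, ...) {
  cat("ALN node parameters (E/I populations)\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
print.global_params <- function(x, ...) {
  cat(sprintf(
    "Global parameters: K_gl = %g, v_gl = %g m/s, sigma_ou = %g, dt = %g ms, %gs (- %gs transient)\n",
    x$K_gl, x$v_gl, x$sigma_ou, x$dt, x$duration, x$transient))
  invisible(x)
}
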