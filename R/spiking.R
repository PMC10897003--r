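#' Monte-Carlo ensemble of uncoupled EIF neurons
#'
#' Euler-Maruyama simulation of `n_neurons` independent exponential
#' integrate-and-fire neurons driven by white noise with mean `mu` and
#' amplitude `sigma`; the stationary ensemble rate is the independent
#' reference for the Fokker-Planck transfer tables.
#'
#' @param neuron A [neuron_params()] object.
#' @param mu Mean input (mV/ms).
#' @param sigma Noise amplitude (mV/sqrt(ms)).
#' @param n_neurons Ensemble size.
#' @param T_s Simulated time (s) including the transient.
#' @param dt Time step (ms).
#' @param transient_s Initial span excluded from the rate estimate (s).
#' @param seed RNG seed.
#' @return List with `rate` (kHz), `n_spikes`, `T_measured_ms`.
#' @export
spiking_eif_rate <- function(neuron, mu, sigma, n_neurons = 10000,
                             T_s = 30, dt = 0.05, transient_s = 1,
                             seed = 1) {
  stopifnot(inherits(neuron, "neuron_params"), sigma > 0, n_neurons > 0)
  eif_mc_rate_cpp(unclass(neuron), mu, sigma, as.integer(n_neurons),
                  T_s * 1000, dt, transient_s * 1000, as.integer(seed))
}

#' Monte-Carlo recurrent AdEx network matching one ALN node
#'
#' Spiking network of `NE` excitatory and `NI` inhibitory AdEx neurons with
#' fixed in-degrees `K_E`/`K_I`, saturating single-exponential synaptic
#' gates incremented by `c_ab * (1 - s)` per presynaptic spike,
#' per-target-population synaptic delays and somatic adaptation on the
#' excitatory population.  The mean-field reduction of this network is the
#' ALN node, making its stationary excitatory rate the independent
#' reference for the mean-field fidelity check.
#'
#' @param neuron A [neuron_params()] object.
#' @param pop A [population_params()] object.
#' @param mu_E_ext,mu_I_ext External mean drives (mV/ms); default to the
#'   values in `pop`.
#' @param NE,NI Population sizes.
#' @param T_s Simulated time (s).
#' @param dt Time step (ms).
#' @param transient_s Span excluded from the rate estimate (s).
#' @param seed RNG seed.
#' @return List with `rate_E` (kHz), `n_spikes_E`, `T_measured_ms`.
#' @export
spiking_adex_node_rate <- function(neuron, pop, mu_E_ext = NULL,
                                   mu_I_ext = NULL, NE = 8000, NI = 2000,
                                   T_s = 20, dt = 0.05, transient_s = 2,
                                   seed = 1) {
  stopifnot(inherits(neuron, "neuron_params"),
            inherits(pop, "population_params"))
  if (is.null(mu_E_ext)) mu_E_ext <- pop$mu_E_ext
  if (is.null(mu_I_ext)) mu_I_ext <- pop$mu_I_ext
  if (NE < pop$K_E || NI < pop$K_I) {
    stop("population sizes must be at least the in-degrees K_E / K_I")
  }
  adex_net_rate_cpp(unclass(neuron), unclass(pop), mu_E_ext, mu_I_ext,
                    as.integer(NE), as.integer(NI), T_s * 1000, dt,
                    transient_s * 1000, as.integer(seed))
}

#' Stationary excitatory rate of a single mean-field node
#'
#' Runs the network integrator on a one-node, zero-coupling connectome and
#' returns the time-averaged post-transient excitatory rate; used for the
#' mean-field versus spiking-network comparison.
#'
#' @param pop A [population_params()] object.
#' @param tables A `transfer_tables` object.
#' @param mu_E_ext Optional override of the external drive onto E.
#' @param sigma_ou Noise amplitude (0 for the deterministic node).
#' @param duration,transient Simulated and discarded time (s).
#' @param seed Seed for the (possibly silent) noise streams.
#' @return Mean excitatory rate in kHz.
#' @export
aln_node_stationary_rate <- function(pop, tables, mu_E_ext = NULL,
                                     sigma_ou = 0, duration = 20,
                                     transient = 5, seed = 1) {
  if (!is.null(mu_E_ext)) pop$mu_E_ext <- mu_E_ext
  glob <- global_params(K_gl = 0, sigma_ou = sigma_ou,
                        duration = duration, transient = transient)
  conn <- connectome(matrix(0, 1, 1), matrix(0, 1, 1), "node")
  sim <- simulate_network(conn, pop, glob, tables, seed = seed)
  mean(sim$rate_E)
}
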