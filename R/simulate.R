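#' One Euler-Maruyama step of the Ornstein-Uhlenbeck background noise
#'
#' `mu' = mu + dt * (-mu / tau_ou) + sigma_ou * sqrt(dt) * xi`, with
#' `xi ~ N(0, 1)` drawn from R's random number stream.  The stationary
#' variance of the process is `sigma_ou^2 * tau_ou / 2`.
#'
#' @param mu_ou Current value (may be a vector; one independent draw each).
#' @param sigma_ou Fluctuation amplitude (mV ms^(-3/2)).
#' @param tau_ou Time constant (ms).
#' @param dt Time step (ms).
#' @return Updated value(s).
#' @export
ou_step <- function(mu_ou, sigma_ou, tau_ou, dt) {
  stopifnot(dt > 0, tau_ou > 0, sigma_ou >= 0)
  mu_ou + dt * (-mu_ou / tau_ou) +
    sigma_ou * sqrt(dt) * rnorm(length(mu_ou))
}

#' Effective input rates and their variances for every node
#'
#' Given delayed population-rate histories, computes the dimensionless
#' effective input rate `r_ab` and its variance `rho_ab` for each of the
#' four projections (EE, EI, IE, II) of every node:
#' `r_ab = c_ab * (K_b * r_b(t - d_ab) + delta_abE * K_gl * sum_j C_ij *
#' r_E,j(t - D_ij))` (dimensionless kHz x ms reading), `rho_ab` likewise
#' with `c_ab^2` and `C_ij^2`.  Inter-regional coupling enters the EE
#' projection only.
#'
#' @param rate_E_hist,rate_I_hist Matrices (regions x time steps) of past
#'   rates in kHz; the last column is the current step.
#' @param conn An [connectome()] object (delays used in integration steps
#'   via `dt`).
#' @param pop A [population_params()] object.
#' @param K_gl Global coupling strength.
#' @param dt Integration step (ms) used to index the delayed columns.
#' @return A list with elements `r` and `rho`, each a list of numeric
#'   vectors `ee`, `ei`, `ie`, `ii` (one value per region).
#' @export
effective_input_rates <- function(rate_E_hist, rate_I_hist, conn, pop, K_gl,
                                  dt = 0.1) {
  stopifnot(inherits(conn, "aln_connectome"),
            inherits(pop, "population_params"))
  n <- conn$n
  Tn <- ncol(rate_E_hist)
  stopifnot(nrow(rate_E_hist) == n, nrow(rate_I_hist) == n,
            ncol(rate_I_hist) == Tn)
  dE <- max(1L, as.integer(round(pop$d_E / dt)))
  dI <- max(1L, as.integer(round(pop$d_I / dt)))
  Dsteps <- matrix(pmax(1L, as.integer(round(conn$D / dt))), n, n)
  need <- max(dE, dI, Dsteps)
  if (Tn <= need) {
    stop(sprintf(
      "history buffer too short: %d columns supplied, need more than %d (max delay)",
      Tn, need))
  }
  rE_dE <- rate_E_hist[, Tn - dE]
  rI_dE <- rate_I_hist[, Tn - dE]
  rE_dI <- rate_E_hist[, Tn - dI]
  rI_dI <- rate_I_hist[, Tn - dI]
  # delayed network input, per edge delay
  net1 <- net2 <- numeric(n)
  for (i in seq_len(n)) {
    rj <- rate_E_hist[cbind(seq_len(n), Tn - Dsteps[i, ])]
    net1[i] <- sum(conn$C[i, ] * rj)
    net2[i] <- sum(conn$C[i, ]^2 * rj)
  }
  aEE <- pop$c_EE
  aIE <- pop$c_IE
  aEI <- pop$c_EI
  aII <- pop$c_II
  r <- list(ee = aEE * (pop$K_E * rE_dE + K_gl * net1),
            ei = aEI * (pop$K_I * rI_dE),
            ie = aIE * (pop$K_E * rE_dI),
            ii = aII * (pop$K_I * rI_dI))
  rho <- list(ee = aEE^2 * (pop$K_E * rE_dE + K_gl * net2),
              ei = aEI^2 * (pop$K_I * rI_dE),
              ie = aIE^2 * (pop$K_E * rE_dI),
              ii = aII^2 * (pop$K_I * rI_dI))
  list(r = r, rho = rho)
}

#' Initial (quiescent) state of one ALN node
#'
#' @param pop A [population_params()] object.
#' @return Named list holding the node state variables.
#' @export
aln_node_state <- function(pop = population_params()) {
  list(mu_E = pop$mu_E_ext, mu_I = pop$mu_I_ext, ou_E = 0, ou_I = 0,
       s_ee = 0, s_ei = 0, s_ie = 0, s_ii = 0,
       v_ee = 0, v_ei = 0, v_ie = 0, v_ii = 0,
       I_A = 0, r_E = 0, r_I = 0, Vbar_E = NA_real_)
}

#' One integration step of a single ALN node
#'
#' Advances the node state by `dt` given precomputed effective input rates.
#' The mean-input equations, adaptation current and noise are forward
#' Euler; the synaptic gate and gate-variance equations treat their linear
#' self-term implicitly, which keeps `s` within 0..1 and the variance
#' non-negative without clamping.  Rates, mean voltage and timescales are
#' refreshed from the transfer tables at the adaptation-shifted mean input.
#'
#' @param state A state list as returned by [aln_node_state()].
#' @param r,rho Lists with elements `ee`, `ei`, `ie`, `ii`: effective input
#'   rates and variances (scalars for a single node).
#' @param tables A `transfer_tables` object.
#' @param pop A [population_params()] object.
#' @param sigma_ou,tau_ou,dt Noise amplitude, noise time constant and step.
#' @param ou_noise Optional pair of standard-normal deviates for the two OU
#'   processes; defaults to draws from R's stream.
#' @return The updated state list.
#' @export
aln_node_step <- function(state, r, rho, tables, pop, sigma_ou = 0,
                          tau_ou = 5, dt = 0.1, ou_noise = NULL) {
  taum <- pop$C / pop$g_L
  sig2 <- function(J1, v1, ts1, r1, J2, v2, ts2, r2) {
    2 * J1^2 * v1 * ts1 * taum / ((1 + r1) * taum + ts1) +
      2 * J2^2 * v2 * ts2 * taum / ((1 + r2) * taum + ts2) +
      pop$sigma_ext^2
  }
  sigE <- sqrt(sig2(pop$J_EE, state$v_ee, pop$tau_s_E, r$ee,
                    pop$J_EI, state$v_ei, pop$tau_s_I, r$ei))
  sigI <- sqrt(sig2(pop$J_IE, state$v_ie, pop$tau_s_E, r$ie,
                    pop$J_II, state$v_ii, pop$tau_s_I, r$ii))
  qE <- lookup(tables, state$mu_E - state$I_A / pop$C, sigE)
  qI <- lookup(tables, state$mu_I, sigI)

  imp_s <- function(s, rab, tau) (s + dt / tau * rab) /
    (1 + dt / tau * (1 + rab))
  imp_v <- function(v, s, rab, rhoab, tau) {
    h <- dt / tau^2
    (v + h * (1 - s)^2 * rhoab) / (1 + h * (2 * tau * (rab + 1) - rhoab))
  }
  new <- state
  new$r_E <- qE$rate
  new$r_I <- qI$rate
  new$Vbar_E <- qE$mean_voltage
  new$mu_E <- state$mu_E + dt *
    (pop$J_EE * state$s_ee + pop$J_EI * state$s_ei + pop$mu_E_ext +
       state$ou_E - state$mu_E) / qE$timescale
  new$mu_I <- state$mu_I + dt *
    (pop$J_IE * state$s_ie + pop$J_II * state$s_ii + pop$mu_I_ext +
       state$ou_I - state$mu_I) / qI$timescale
  new$s_ee <- imp_s(state$s_ee, r$ee, pop$tau_s_E)
  new$s_ei <- imp_s(state$s_ei, r$ei, pop$tau_s_I)
  new$s_ie <- imp_s(state$s_ie, r$ie, pop$tau_s_E)
  new$s_ii <- imp_s(state$s_ii, r$ii, pop$tau_s_I)
  new$v_ee <- imp_v(state$v_ee, state$s_ee, r$ee, rho$ee, pop$tau_s_E)
  new$v_ei <- imp_v(state$v_ei, state$s_ei, r$ei, rho$ei, pop$tau_s_I)
  new$v_ie <- imp_v(state$v_ie, state$s_ie, r$ie, rho$ie, pop$tau_s_E)
  new$v_ii <- imp_v(state$v_ii, state$s_ii, r$ii, rho$ii, pop$tau_s_I)
  new$I_A <- state$I_A + dt *
    ((pop$alpha * (qE$mean_voltage - pop$E_A) - state$I_A) / pop$tau_A +
       pop$beta * qE$rate)
  if (is.null(ou_noise)) ou_noise <- rnorm(2)
  new$ou_E <- state$ou_E + dt * (-state$ou_E / tau_ou) +
    sigma_ou * sqrt(dt) * ou_noise[1]
  new$ou_I <- state$ou_I + dt * (-state$ou_I / tau_ou) +
    sigma_ou * sqrt(dt) * ou_noise[2]
  new
}

#' Derive per-population noise stream seeds from a master seed
#'
#' A virtual subject is one master seed; it deterministically spawns one
#' independent stream seed per population per region, so a node embedded
#' in a network sees exactly the same noise as the same node simulated
#' alone with its stream seeds.
#'
#' @param seed Master seed (integer).
#' @param n Number of regions.
#' @return Integer vector of length `2n` (E stream, I stream per region).
#' @export
make_stream_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max, 2L * n))
}

#' Simulate the delay-coupled whole-brain ALN network
#'
#' Full-network Euler integration with per-edge delay buffers and
#' independent Ornstein-Uhlenbeck noise per population per region.  The
#' first `transient` seconds are discarded.  Identical (connectome,
#' parameters, seed) yield bit-identical output.
#'
#' @param conn An [connectome()] object.
#' @param pop A [population_params()] object.
#' @param glob A [global_params()] object.
#' @param tables A `transfer_tables` object.
#' @param seed Master seed of the virtual subject.
#' @param output_dt Sampling step of the stored excitatory rate traces (ms).
#' @param stream_seeds Optional explicit per-stream seeds (length `2n`),
#'   overriding the master-seed derivation.
#' @return An object of class `aln_sim`: `rate_E` (regions x time, kHz),
#'   `time_ms`, `rate_I_mean`, clamp-event counters and full provenance
#'   (parameters, seeds, output step).
#' @export
simulate_network <- function(conn, pop, glob, tables, seed,
                             output_dt = 1, stream_seeds = NULL) {
  stopifnot(inherits(conn, "aln_connectome"),
            inherits(pop, "population_params"),
            inherits(glob, "global_params"),
            inherits(tables, "transfer_tables"))
  out_every <- as.integer(round(output_dt / glob$dt))
  stopifnot(out_every >= 1)
  if (is.null(stream_seeds)) stream_seeds <- make_stream_seeds(seed, conn$n)
  stopifnot(length(stream_seeds) == 2 * conn$n)
  Dsteps <- matrix(as.integer(round(conn$D / glob$dt)), conn$n, conn$n)
  res <- aln_simulate_cpp(conn$C, Dsteps, unclass(pop), unclass(glob),
                          tables[c("mu_grid", "sigma_grid", "r_table",
                                   "V_table", "tau_table")],
                          as.numeric(stream_seeds), out_every)
  if (any(!is.finite(res$rate_E))) {
    stop("non-finite rate trace returned by the integrator")
  }
  t0 <- glob$transient * 1000
  out <- list(rate_E = res$rate_E,
              time_ms = t0 + (seq_len(ncol(res$rate_E)) - 1) * output_dt,
              rate_I_mean = res$rate_I_mean,
              clamp_events_s = res$clamp_events_s,
              clamp_events_var = res$clamp_events_var,
              labels = conn$labels,
              provenance = list(seed = seed,
                                stream_seeds = as.integer(stream_seeds),
                                pop = unclass(pop), glob = unclass(glob),
                                output_dt = output_dt,
                                n_regions = conn$n))
  class(out) <- "aln_sim"
  out
}

#' @export
print.aln_sim <- function(x, ...) {
  cat(sprintf(
    "ALN simulation: %d regions x %d samples (%.1f s post-transient), mean E rate %.2f Hz\n",
    nrow(x$rate_E), ncol(x$rate_E),
    diff(range(x$time_ms)) / 1000, 1000 * mean(x$rate_E)))
  invisible(x)
}
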