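# Shared fixtures, built once per test run and cached.

.aln_cache <- new.env(parent = emptyenv())

# Transfer tables on a grid wide enough for the high-drive fidelity checks
# (mu up to 10 mV/ms) but coarser than the package default, so the whole
# suite pays the Fokker-Planck build cost once.
aln_test_tables <- function() {
  if (is.null(.aln_cache$tables)) {
    .aln_cache$tables <- build_transfer_tables(
      neuron_params(),
      mu_grid = seq(-2, 10, by = 0.1),
      sigma_grid = seq(0.1, 5, by = 0.2))
  }
  .aln_cache$tables
}

# Small delay-free two-node connectome for decoupling/symmetry contracts.
aln_two_node_conn <- function(coupled = TRUE) {
  C <- matrix(0, 2, 2)
  if (coupled) C[1, 2] <- C[2, 1] <- 1
  connectome(C, matrix(2, 2, 2) - 2 * diag(2), c("a", "b"))
}

aln_small_net <- function(n = 20, seed = 3) {
  key <- sprintf("net_%d_%d", n, seed)
  if (is.null(.aln_cache[[key]])) {
    .aln_cache[[key]] <- synth_connectome(n_regions = n, seed = seed)
  }
  .aln_cache[[key]]
}

# narrowband test signal (single frequency, unit amplitude)
sine_bold <- function(freq_hz, T_s, TR, phase = 0) {
  t <- seq(0, T_s - TR, by = TR)
  sin(2 * pi * freq_hz * t + phase)
}

# independent narrowband (0.04-0.07 Hz) noise generator for metric oracles
narrowband_test_signal <- function(T, TR, f1 = 0.04, f2 = 0.07) {
  freqs <- (seq_len(T) - 1) / (T * TR)
  freqs <- pmin(freqs, 1 / TR - freqs)
  keep <- freqs >= f1 & freqs <= f2
  X <- fft(rnorm(T))
  X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE) / T)
  y / sd(y)
}
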