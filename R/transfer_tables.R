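#' Solver settings for the transfer-table builder
#'
#' @param dV Voltage discretisation of the threshold integration (mV).
#' @param V_lb Lower voltage bound of the integration domain (mV).
#' @param f_tau Probe frequency (Hz) at which the one-pole (exponential
#'   filter) timescale is fitted to the linear rate response.
#' @param rate_floor Rates below this value (kHz) are treated as quiescent:
#'   the timescale falls back to the membrane time constant there.
#' @param interp_rel_tol Declared relative tolerance of bilinear
#'   interpolation between grid nodes, for rates above 1 Hz and (for the
#'   timescale surface) outside the degenerate corner where the one-pole
#'   fit reaches its lower floor; checked against a refined-grid build in
#'   the test suite.
#'
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(dV = 0.01, V_lb = -200, f_tau = 5,
                            rate_floor = 1e-9, interp_rel_tol = 0.05) {
  stopifnot(dV > 0, V_lb < -100, f_tau > 0, rate_floor > 0)
  s <- list(dV = dV, V_lb = V_lb, f_tau = f_tau, rate_floor = rate_floor,
            interp_rel_tol = interp_rel_tol)
  class(s) <- "solver_settings"
  s
}

#' Build population transfer tables from the Fokker-Planck equation
#'
#' Computes, on a rectangular grid of mean input `mu` (mV/ms) and noise
#' amplitude `sigma` (mV/sqrt(ms)), the stationary population rate
#' `Phi_r` (kHz), the stationary mean membrane voltage `Phi_V` (mV, with the
#' refractory probability mass placed at the reset potential) and the
#' effective timescale `Phi_tau` (ms) of the linearised rate response, for
#' an exponential integrate-and-fire population with reset and refractory
#' period.  The stationary solution is obtained by threshold integration of
#' the Fokker-Planck equation; the timescale by a one-pole fit to the
#' linear response at a single low probe frequency.
#'
#' Adaptation is deliberately not part of the tables: the mean adaptation
#' current shifts the queried `mu` at simulation time (adiabatic treatment).
#'
#' @param neuron A [neuron_params()] object.
#' @param mu_grid Ascending grid of mean inputs (mV/ms).
#' @param sigma_grid Ascending grid of noise amplitudes (mV/sqrt(ms)),
#'   all positive.
#' @param solver A [solver_settings()] object.
#'
#' @return An object of class `transfer_tables` with elements `mu_grid`,
#'   `sigma_grid`, `r_table`, `V_table`, `tau_table`, `flag` (0 = ok,
#'   1 = quiescent timescale fallback, 2 = failed point) and `provenance`.
#' @export
build_transfer_tables <- function(neuron = neuron_params(),
                                  mu_grid = seq(-2, 6, by = 0.05),
                                  sigma_grid = seq(0.1, 5, by = 0.1),
                                  solver = solver_settings()) {
  stopifnot(inherits(neuron, "neuron_params"),
            inherits(solver, "solver_settings"))
  if (length(mu_grid) < 2 || length(sigma_grid) < 2) {
    stop("grids must contain at least two points")
  }
  if (is.unsorted(mu_grid, strictly = TRUE) ||
      is.unsorted(sigma_grid, strictly = TRUE)) {
    stop("grids must be strictly ascending")
  }
  if (any(sigma_grid <= 0)) stop("all sigma grid values must be positive")

  w_tau <- 2 * pi * solver$f_tau / 1000  # Hz -> rad/ms
  res <- fp_transfer_tables_cpp(unclass(neuron), mu_grid, sigma_grid,
                                solver$dV, solver$V_lb, w_tau,
                                solver$rate_floor)
  if (any(res$flag == 2L)) {
    bad <- which(res$flag == 2L, arr.ind = TRUE)
    warning(sprintf(
      "non-convergent integration at %d grid point(s), e.g. mu = %g, sigma = %g; affected entries are flagged",
      nrow(bad), mu_grid[bad[1, 1]], sigma_grid[bad[1, 2]]))
  }
  tt <- list(mu_grid = as.numeric(mu_grid),
             sigma_grid = as.numeric(sigma_grid), r_table = res$r,
             V_table = res$V, tau_table = res$tau, flag = res$flag,
             provenance = list(neuron = unclass(neuron),
                               solver = unclass(solver)))
  class(tt) <- "transfer_tables"
  tt
}

#' Query transfer tables
#'
#' Bilinear interpolation of the three transfer surfaces; queries outside
#' the grid clamp to the boundary value.
#'
#' @param tables A `transfer_tables` object.
#' @param mu,sigma Numeric vectors of equal length (recycled if scalar).
#'
#' @return A list with numeric vectors `rate` (kHz), `mean_voltage` (mV)
#'   and `timescale` (ms).
#' @export
lookup <- function(tables, mu, sigma) {
  stopifnot(inherits(tables, "transfer_tables"))
  k <- max(length(mu), length(sigma))
  mu <- rep_len(as.numeric(mu), k)
  sigma <- rep_len(as.numeric(sigma), k)
  tables_lookup_cpp(tables$mu_grid, tables$sigma_grid, tables$r_table,
                    tables$V_table, tables$tau_table, mu, sigma)
}

#' Write/read a transfer-table archive
#'
#' The archive stores both grids, all three surfaces, flags and the full
#' provenance (neuron parameters and solver settings) in one file; a
#' round-trip is bit-identical.
#'
#' @param tables A `transfer_tables` object.
#' @param path File path of the archive.
#' @return `write_transfer_tables()` returns `path` invisibly;
#'   `read_transfer_tables()` returns the `transfer_tables` object.
#' @export
write_transfer_tables <- function(tables, path) {
  stopifnot(inherits(tables, "transfer_tables"))
  saveRDS(tables, path, version = 3)
  invisible(path)
}

#' @rdname write_transfer_tables
#' @export
read_transfer_tables <- function(path) {
  tt <- readRDS(path)
  if (!inherits(tt, "transfer_tables")) {
    stop("'", path, "' does not contain a transfer_tables archive")
  }
  tt
}

#' @export
print.transfer_tables <- function(x, ...) {
  cat(sprintf(
    "Transfer tables: %d x %d grid, mu in [%g, %g] mV/ms, sigma in [%g, %g] mV/sqrt(ms)\n",
    length(x$mu_grid), length(x$sigma_grid), min(x$mu_grid), max(x$mu_grid),
    min(x$sigma_grid), max(x$sigma_grid)))
  cat(sprintf("  rate range %.4g - %.4g kHz; %d flagged point(s)\n",
              min(x$r_table), max(x$r_table), sum(x$flag == 2L)))
  invisible(x)
}
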