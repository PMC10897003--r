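#' Evolutionary (population-based) parameter search
#'
#' Real-coded evolutionary optimisation used to fit node parameters to a
#' target functional-connectivity matrix: an initial population of
#' `n_init` individuals is drawn uniformly within the bounds; each
#' generation keeps the elite, fills the population by tournament
#' selection, blend crossover and Gaussian mutation (standard deviation a
#' fraction of the bound span, decaying geometrically), and re-evaluates.
#' The search maximises `objective`.  Individuals whose objective errors
#' or returns a non-finite value are discarded (logged), never aborting
#' the run.  Identical seeds give identical traces.
#'
#' @param objective Function of a parameter vector returning a scalar to
#'   maximise.
#' @param bounds Two-row matrix (lower/upper) with one column per
#'   parameter; column names name the parameters.
#' @param n_init Size of the initial random population.
#' @param n_pop Population size per generation.
#' @param n_gen Number of generations.
#' @param seed RNG seed.
#' @param elite_frac Fraction of the population copied unchanged.
#' @param mutate_frac Initial mutation standard deviation as a fraction of
#'   each parameter's span.
#' @param mutate_decay Geometric decay of the mutation scale per
#'   generation.
#' @return List with `best_par`, `best_value`, `trace` (tibble with
#'   generation, best-so-far and population mean), `n_failed`, `seed`.
#' @export
evolutionary_fit <- function(objective, bounds, n_init = 160, n_pop = 80,
                             n_gen = 100, seed = 1, elite_frac = 0.25,
                             mutate_frac = 0.1, mutate_decay = 0.98) {
  bounds <- as.matrix(bounds)
  stopifnot(nrow(bounds) == 2, all(bounds[2, ] > bounds[1, ]),
            n_init >= 2, n_pop >= 2, n_gen >= 1)
  d <- ncol(bounds)
  span <- bounds[2, ] - bounds[1, ]
  n_failed <- 0L

  eval1 <- function(par) {
    v <- tryCatch(objective(par), error = function(e) NA_real_)
    if (!is.finite(v)) {
      n_failed <<- n_failed + 1L
      v <- -Inf
    }
    v
  }

  withr::with_seed(as.integer(seed), {
    pop <- matrix(runif(n_init * d, bounds[1, ], bounds[2, ]),
                  ncol = d, byrow = TRUE)
    colnames(pop) <- colnames(bounds)
    fit <- apply(pop, 1, eval1)
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[ord[seq_len(min(n_pop, n_init))], , drop = FALSE]
    fit <- fit[ord[seq_len(min(n_pop, n_init))]]

    trace <- vector("list", n_gen + 1)
    trace[[1]] <- tibble::tibble(generation = 0L, best = max(fit),
                                 mean = mean(fit[is.finite(fit)]))
    n_elite <- max(1L, round(elite_frac * n_pop))
    for (gen in seq_len(n_gen)) {
      sig <- mutate_frac * mutate_decay^(gen - 1) * span
      ord <- order(fit, decreasing = TRUE)
      pop <- pop[ord, , drop = FALSE]
      fit <- fit[ord]
      newpop <- pop[seq_len(n_elite), , drop = FALSE]
      while (nrow(newpop) < n_pop) {
        # binary tournaments
        pick <- function() {
          ij <- sample.int(nrow(pop), 2)
          ij[which.max(fit[ij])]
        }
        pa <- pop[pick(), ]
        pb <- pop[pick(), ]
        w <- runif(d)
        child <- w * pa + (1 - w) * pb + rnorm(d, 0, sig)
        child <- pmin(pmax(child, bounds[1, ]), bounds[2, ])
        newpop <- rbind(newpop, child)
      }
      newfit <- c(fit[seq_len(n_elite)],
                  apply(newpop[-seq_len(n_elite), , drop = FALSE], 1,
                        eval1))
      pop <- newpop
      fit <- newfit
      trace[[gen + 1]] <- tibble::tibble(generation = gen,
                                         best = max(fit),
                                         mean = mean(fit[is.finite(fit)]))
    }
    best <- which.max(fit)
    list(best_par = pop[best, ], best_value = fit[best],
         trace = do.call(rbind, trace), n_failed = n_failed, seed = seed)
  })
}

#' Default fitting bounds for the node-parameter search
#'
#' Uniform initialisation intervals for the five fitted parameters:
#' external drives onto E and I (mV/ms), noise amplitude, and the two
#' adaptation parameters.
#'
#' @return Two-row bounds matrix for [evolutionary_fit()].
#' @export
fit_bounds <- function() {
  b <- rbind(lower = c(mu_E_ext = 0, mu_I_ext = 0, sigma_ou = 0,
                       alpha = 0, beta = 0),
             upper = c(mu_E_ext = 4, mu_I_ext = 4, sigma_ou = 0.3,
                       alpha = 40, beta = 40))
  b
}

#' Objective: correlation between simulated and target FC
#'
#' Builds the default fitting objective: given a named parameter vector
#' (any of `mu_E_ext`, `mu_I_ext`, `sigma_ou`, `alpha`, `beta`), simulate
#' the network for one fixed seed, convert to BOLD and return the Pearson
#' correlation between the lower triangles of the simulated and target FC
#' matrices.
#'
#' @param target_fc Target functional-connectivity matrix.
#' @param conn,pop,glob,tables Model ingredients (defaults perturbed by
#'   the parameter vector).
#' @param seed Simulation seed held fixed across evaluations so the
#'   objective is deterministic.
#' @param TR BOLD repetition time (s).
#' @return Function suitable for [evolutionary_fit()].
#' @export
fc_objective <- function(target_fc, conn, pop, glob, tables, seed = 1,
                         TR = 2) {
  target_lower <- target_fc[lower.tri(target_fc)]
  function(par) {
    for (nm in names(par)) {
      if (nm %in% c("mu_E_ext", "mu_I_ext", "alpha", "beta")) {
        pop[[nm]] <- par[[nm]]
      } else if (nm == "sigma_ou") {
        glob$sigma_ou <- par[[nm]]
      } else {
        stop("unknown fitted parameter: ", nm)
      }
    }
    sim <- simulate_network(conn, pop, glob, tables, seed = seed)
    bold <- bold_from_rates(sim, TR_s = TR)
    FC <- functional_connectivity(bold)
    cor(FC[lower.tri(FC)], target_lower)
  }
}
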