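test_that("parameter constructors enforce their invariants", {
  np <- neuron_params()
  expect_equal(np$tau_m, np$C / np$g_L)
  expect_error(neuron_params(V_s = -55), "V_s")
  expect_error(neuron_params(C = -1))
  expect_error(population_params(J_EI = 1), "negative")
  expect_error(global_params(duration = 3, transient = 5), "transient")
})

test_that("rate surface is non-negative, monotone in mu, bounded by 1/T_ref", {
  tt <- aln_test_tables()
  expect_true(all(is.finite(tt$r_table)))
  expect_true(all(tt$r_table >= 0))
  expect_true(all(tt$tau_table > 0))
  expect_true(all(is.finite(tt$V_table)))
  # monotone non-decreasing in mu at every sigma
  expect_true(all(apply(tt$r_table, 2, function(col) all(diff(col) >= -1e-12))))
  # refractory bound
  expect_true(all(tt$r_table < 1 / neuron_params()$T_ref))
  # far subthreshold quiescence
  q <- lookup(tt, -2, 0.5)
  expect_lt(q$rate, 1e-4)
})

test_that("lookup reproduces grid nodes exactly and stays convex between them", {
  tt <- aln_test_tables()
  i <- 45; j <- 9
  q <- lookup(tt, tt$mu_grid[i], tt$sigma_grid[j])
  expect_identical(q$rate, tt$r_table[i, j])
  expect_identical(q$mean_voltage, tt$V_table[i, j])
  expect_identical(q$timescale, tt$tau_table[i, j])
  # midpoint query within min/max of the four surrounding nodes
  mu_m <- mean(tt$mu_grid[i:(i + 1)])
  sg_m <- mean(tt$sigma_grid[j:(j + 1)])
  q <- lookup(tt, mu_m, sg_m)
  corner <- tt$r_table[i:(i + 1), j:(j + 1)]
  expect_gte(q$rate, min(corner))
  expect_lte(q$rate, max(corner))
  # out-of-grid queries clamp to the boundary
  expect_identical(lookup(tt, -50, 1.1)$rate, lookup(tt, min(tt$mu_grid), 1.1)$rate)
  expect_error(lookup(tt, NaN, 1), "mu")
  expect_error(lookup(tt, 1, Inf), "sigma")
})

test_that("interpolation error against a 4x refined grid is within the declared tolerance", {
  tt <- aln_test_tables()
  tol <- tt$provenance$solver$interp_rel_tol
  fine <- build_transfer_tables(
    neuron_params(),
    mu_grid = seq(0.5, 4.5, by = 0.025),
    sigma_grid = seq(0.5, 3, by = 0.05))
  set.seed(7)
  mu_q <- runif(100, 0.6, 4.4)
  sg_q <- runif(100, 0.6, 2.9)
  a <- lookup(tt, mu_q, sg_q)
  b <- lookup(fine, mu_q, sg_q)
  keep <- b$rate > 1e-3  # > 1 Hz, where relative error is meaningful
  expect_gt(sum(keep), 30)
  expect_lt(max(abs(a$rate[keep] / b$rate[keep] - 1)), tol)
  # the timescale surface is non-smooth where the one-pole fit reaches its
  # floor (burst-onset corner); the declared tolerance covers the
  # well-posed region above twice the floor
  keep_tau <- keep & b$timescale > 0.25
  expect_gt(sum(keep_tau), 30)
  expect_lt(max(abs(a$timescale[keep_tau] / b$timescale[keep_tau] - 1)), tol)
})

test_that("table archive round-trips bit-identically", {
  tt <- aln_test_tables()
  f <- tempfile(fileext = ".rds")
  write_transfer_tables(tt, f)
  tt2 <- read_transfer_tables(f)
  expect_identical(tt, tt2)
  saveRDS(1:3, f)
  expect_error(read_transfer_tables(f), "archive")
})

test_that("grid validation rejects malformed inputs", {
  expect_error(build_transfer_tables(mu_grid = c(1, 0.5, 2),
                                     sigma_grid = c(0.5, 1)), "ascending")
  expect_error(build_transfer_tables(mu_grid = c(0, 1),
                                     sigma_grid = c(-1, 1)), "positive")
})

test_that("Fokker-Planck rates agree with an EIF Monte-Carlo ensemble", {
  tt <- aln_test_tables()
  pts <- list(c(1.5, 1.5), c(2, 2.5), c(3, 1.5))
  for (k in seq_along(pts)) {
    mu <- pts[[k]][1]; sg <- pts[[k]][2]
    fp <- lookup(tt, mu, sg)$rate
    mc <- spiking_eif_rate(neuron_params(), mu, sg, n_neurons = 2000,
                           T_s = 10, dt = 0.1, transient_s = 1,
                           seed = 40 + k)
    expect_gt(mc$rate, 1e-3)  # > 1 Hz regime
    expect_lt(abs(fp / mc$rate - 1), 0.2)
  }
})
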