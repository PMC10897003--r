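test_that("noiseless OU dynamics: fixed point and exponential relaxation", {
  expect_equal(ou_step(0, 0, 5, 0.1), 0)
  # deterministic decay from 1 with tau = 5 ms
  x <- 1
  for (k in 1:500) x <- ou_step(x, 0, 5, 0.1)
  expect_equal(x, exp(-50 / 5), tolerance = 0.01)
})

test_that("OU stationary variance matches sigma^2 tau / 2 within 5%", {
  tau <- 5; sig <- 0.19; dt <- 0.1
  nchain <- 2000
  withr::with_seed(99, {
    x <- numeric(nchain)
    burn <- 1000
    keep <- 500
    acc <- numeric(0)
    for (k in seq_len(burn + keep)) {
      x <- ou_step(x, sig, tau, dt)
      if (k > burn) acc <- c(acc, x)
    }
    expect_equal(var(acc), sig^2 * tau / 2, tolerance = 0.05)
  })
})

test_that("effective input rates reduce to the printed uncoupled form", {
  pop <- population_params()
  conn <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  rE <- matrix(0.01, 1, 60)
  rI <- matrix(0.004, 1, 60)
  eff <- effective_input_rates(rE, rI, conn, pop, K_gl = 0)
  expect_equal(eff$r$ee, pop$c_EE * pop$K_E * 0.01)
  expect_equal(eff$r$ei, pop$c_EI * pop$K_I * 0.004)
  expect_equal(eff$rho$ee, pop$c_EE^2 * pop$K_E * 0.01)
})

test_that("a single edge propagates the partner rate with the edge delay", {
  pop <- population_params()
  conn <- aln_two_node_conn()
  Tn <- 100
  rE <- matrix(0, 2, Tn)
  dsteps <- round(conn$D[1, 2] / 0.1)
  rho <- 0.02
  rE[2, Tn - dsteps] <- rho  # only node 2 fired, exactly one delay ago
  rI <- matrix(0, 2, Tn)
  eff <- effective_input_rates(rE, rI, conn, pop, K_gl = 250)
  expect_equal(eff$r$ee[1], pop$c_EE * 250 * rho)
  expect_equal(eff$r$ee[2], 0)
})

test_that("network input sums equal a brute-force double loop", {
  pop <- population_params()
  set.seed(21)
  n <- 5
  M <- matrix(rexp(n^2), n)
  C <- process_fiber_counts(M)
  D <- symmetrize(matrix(runif(n^2, 1, 4), n))
  conn <- connectome(C, D)
  Tn <- 80
  rE <- matrix(runif(n * Tn, 0, 0.05), n)
  rI <- matrix(runif(n * Tn, 0, 0.05), n)
  K_gl <- 250
  eff <- effective_input_rates(rE, rI, conn, pop, K_gl, dt = 0.1)
  # naive loops
  Dsteps <- matrix(pmax(1, round(conn$D / 0.1)), n, n)
  dE <- round(pop$d_E / 0.1)
  for (i in seq_len(n)) {
    s1 <- 0; s2 <- 0
    for (j in seq_len(n)) {
      s1 <- s1 + conn$C[i, j] * rE[j, Tn - Dsteps[i, j]]
      s2 <- s2 + conn$C[i, j]^2 * rE[j, Tn - Dsteps[i, j]]
    }
    expect_equal(eff$r$ee[i],
                 pop$c_EE * (pop$K_E * rE[i, Tn - dE] + K_gl * s1),
                 tolerance = 1e-12)
    expect_equal(eff$rho$ee[i],
                 pop$c_EE^2 * (pop$K_E * rE[i, Tn - dE] + K_gl * s2),
                 tolerance = 1e-12)
  }
  # buffer underrun names the required depth
  expect_error(effective_input_rates(rE[, 1:10], rI[, 1:10], conn, pop,
                                     K_gl), "history buffer")
})

test_that("the quiescent node stays silent and adaptation decays when disabled", {
  tt <- aln_test_tables()
  pop <- population_params(mu_E_ext = 0, mu_I_ext = 0)
  st <- aln_node_state(pop)
  zero <- list(ee = 0, ei = 0, ie = 0, ii = 0)
  for (k in 1:500) st <- aln_node_step(st, zero, zero, tt, pop,
                                       ou_noise = c(0, 0))
  expect_lt(st$r_E, 1e-3)
  expect_equal(st$s_ee, 0)
  expect_equal(st$v_ee, 0)
  # adaptation decays to zero with alpha = beta = 0
  pop2 <- population_params(alpha = 0, beta = 0)
  st <- aln_node_state(pop2)
  st$I_A <- 300
  for (k in 1:400) st <- aln_node_step(st, zero, zero, tt, pop2,
                                       ou_noise = c(0, 0))
  expect_equal(st$I_A, 300 * exp(-400 * 0.1 / pop2$tau_A), tolerance = 0.02)
})

test_that("simulation is bit-identical under the same seed", {
  tt <- aln_test_tables()
  sc <- aln_small_net(10, 11)
  glob <- global_params(duration = 4, transient = 1)
  s1 <- simulate_network(sc$conn, population_params(), glob, tt, seed = 5)
  s2 <- simulate_network(sc$conn, population_params(), glob, tt, seed = 5)
  expect_identical(s1$rate_E, s2$rate_E)
  s3 <- simulate_network(sc$conn, population_params(), glob, tt, seed = 6)
  expect_false(identical(s1$rate_E, s3$rate_E))
})

test_that("disconnected nodes with identical noise streams follow identical trajectories", {
  tt <- aln_test_tables()
  conn <- aln_two_node_conn(coupled = FALSE)
  glob <- global_params(duration = 4, transient = 0.5)
  sim <- simulate_network(conn, population_params(), glob, tt, seed = 1,
                          stream_seeds = c(11, 12, 11, 12))
  expect_identical(sim$rate_E[1, ], sim$rate_E[2, ])
})

test_that("with K_gl = 0 the network decouples into single-node runs", {
  tt <- aln_test_tables()
  conn2 <- aln_two_node_conn(coupled = TRUE)
  glob <- global_params(K_gl = 0, duration = 4, transient = 0.5)
  net <- simulate_network(conn2, population_params(), glob, tt, seed = 1,
                          stream_seeds = c(31, 32, 41, 42))
  conn1 <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  one_a <- simulate_network(conn1, population_params(), glob, tt, seed = 1,
                            stream_seeds = c(31, 32))
  one_b <- simulate_network(conn1, population_params(), glob, tt, seed = 1,
                            stream_seeds = c(41, 42))
  expect_identical(net$rate_E[1, ], one_a$rate_E[1, ])
  expect_identical(net$rate_E[2, ], one_b$rate_E[1, ])
})

test_that("default-condition run keeps gates in bounds without clamping and rates bounded", {
  tt <- aln_test_tables()
  sc <- aln_small_net(20, 3)
  glob <- global_params(duration = 10, transient = 1)
  sim <- simulate_network(sc$conn, population_params(), glob, tt, seed = 2)
  expect_equal(sim$clamp_events_s, 0)
  expect_equal(sim$clamp_events_var, 0)
  expect_true(all(sim$rate_E >= 0))
  expect_true(all(sim$rate_E <= 0.2))
  expect_true(all(is.finite(sim$rate_E)))
})

test_that("halving dt changes the mean rate of a noiseless run by < 2%", {
  tt <- aln_test_tables()
  conn <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  pop <- population_params(mu_E_ext = 3.0)
  r <- sapply(c(0.1, 0.05), function(dt) {
    glob <- global_params(K_gl = 0, sigma_ou = 0, dt = dt, duration = 8,
                          transient = 2)
    mean(simulate_network(conn, pop, glob, tt, seed = 1)$rate_E)
  })
  expect_gt(r[2], 0)
  expect_lt(abs(r[1] / r[2] - 1), 0.02)
})
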