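test_that("functional connectivity matches a covariance/sd oracle", {
  set.seed(11)
  m <- matrix(rnorm(5 * 50), 5)
  FC <- functional_connectivity(m)
  expect_equal(diag(FC), rep(1, 5))
  # brute-force pairwise oracle
  for (i in 1:5) for (j in 1:5) {
    num <- mean((m[i, ] - mean(m[i, ])) * (m[j, ] - mean(m[j, ])))
    ora <- num / (sd(m[i, ]) * sd(m[j, ])) * 50 / 49 * 49 / 50
    expect_equal(FC[i, j], cov(m[i, ], m[j, ]) / (sd(m[i, ]) * sd(m[j, ])),
                 tolerance = 1e-12)
  }
  expect_equal(functional_connectivity(rbind(m[1, ], -m[1, ]))[1, 2], -1)
  m2 <- m; m2[3, ] <- 2
  expect_error(functional_connectivity(m2), "region\\(s\\): 3")
  expect_error(functional_connectivity(m[, 1:2]), "3 time points")
})

test_that("GBC follows the declared diagonal convention and a loop oracle", {
  FCu <- matrix(0.4, 4, 4); diag(FCu) <- 1
  g <- gbc(FCu)
  expect_equal(g$gbc_region, rep(0.4, 4))
  expect_equal(g$gbc_global, 0.4)
  FC2 <- matrix(c(1, 0.7, 0.7, 1), 2)
  expect_equal(gbc(FC2)$gbc_region, c(0.7, 0.7))
  set.seed(12)
  m <- matrix(rnorm(6 * 40), 6)
  FC <- functional_connectivity(m)
  for (include in c(FALSE, TRUE)) {
    g <- gbc(FC, include_self = include)
    ora <- sapply(1:6, function(i) {
      js <- if (include) 1:6 else setdiff(1:6, i)
      sum(FC[i, js]) / length(js)
    })
    expect_equal(g$gbc_region, ora, tolerance = 1e-12)
    expect_equal(g$gbc_global, mean(ora), tolerance = 1e-12)
  }
  # invariance under a simultaneous permutation
  p <- sample(6)
  expect_equal(sort(gbc(FC[p, p])$gbc_region), sort(gbc(FC)$gbc_region))
})

test_that("sub-network averages equal a group-by oracle including super-groups", {
  part1 <- partition(rep("Def", 5))
  g1 <- subnetwork_gbc(1:5 / 10, part1)
  expect_equal(g1$gbc[g1$group == "Def"], mean(1:5 / 10))
  expect_equal(g1$gbc[g1$group == "association"], mean(1:5 / 10))
  expect_true(is.nan(g1$gbc[g1$group == "sensory"]))

  labs <- c(rep("SomMot", 3), rep("Def", 2))
  vals <- c(rep(0.2, 3), rep(0.5, 2))
  g2 <- subnetwork_gbc(vals, partition(labs))
  expect_equal(g2$gbc[g2$group == "SomMot"], 0.2)
  expect_equal(g2$gbc[g2$group == "Def"], 0.5)
  expect_equal(g2$gbc[g2$group == "sensory"], 0.2)

  set.seed(13)
  part <- synth_partition(40, seed = 2)
  vals <- rnorm(40)
  g3 <- subnetwork_gbc(vals, part)
  for (k in seq_len(nrow(g3))) {
    grp <- g3$group[k]
    sel <- if (grp == "association") part$network %in% part$association
      else if (grp == "sensory") part$network %in% part$sensory
      else part$network == grp
    expect_equal(g3$gbc[k], mean(vals[sel]))
  }
  expect_error(partition(c("Def", "bogus")), "bogus")
})

test_that("band-pass keeps the passband and suppresses the stopband", {
  TR <- 2
  x_in <- sine_bold(0.055, 600, TR)
  y_in <- bandpass(rbind(x_in), TR_s = TR)[1, ]
  mid <- 50:250  # away from edges
  amp_ratio <- sd(y_in[mid]) / sd(x_in[mid])
  expect_gt(amp_ratio, 0.9)
  x_out <- sine_bold(0.2, 600, TR)
  y_out <- bandpass(rbind(x_out), TR_s = TR)[1, ]
  expect_lt(sd(y_out[mid]) / sd(x_out[mid]), 0.1)
  expect_error(bandpass(rbind(x_in), TR_s = 10), "Nyquist")
})

test_that("band-passed white noise loses >= 90% of its out-of-band power", {
  set.seed(14)
  TR <- 2; Tn <- 512
  x <- rnorm(Tn)
  y <- bandpass(rbind(x), TR_s = TR)[1, ]
  freqs <- (0:(Tn - 1)) / (Tn * TR)
  freqs <- pmin(freqs, 1 / TR - freqs)
  outb <- freqs < 0.03 | freqs > 0.08
  pow <- function(v) Mod(fft(v))^2
  expect_lt(sum(pow(y)[outb]) / sum(pow(x)[outb]), 0.1)
})

test_that("Kuramoto measures match an explicit phasor-sum oracle and limits", {
  TR <- 2
  x <- sine_bold(0.05, 400, TR)
  ident <- matrix(rep(x, 6), 6, byrow = TRUE)
  ku <- kuramoto(ident)
  expect_true(all(ku$R_t > 1 - 1e-9))
  expect_lt(ku$metastability, 1e-9)

  balanced <- t(sapply(c(0, pi / 2, pi, 3 * pi / 2),
                       function(ph) sine_bold(0.05, 400, TR, phase = ph)))
  kb <- kuramoto(balanced)
  expect_lt(kb$mean_R, 0.05)

  set.seed(15)
  rb <- t(replicate(6, narrowband_test_signal(200, TR)))
  kr <- kuramoto(rb)
  phi <- kr$phi
  R_oracle <- sapply(seq_len(ncol(phi)), function(t)
    Mod(sum(exp(1i * phi[, t]))) / nrow(phi))
  expect_equal(kr$R_t, R_oracle, tolerance = 1e-10)
  expect_true(all(kr$R_t >= 0 & kr$R_t <= 1 + 1e-12))
  expect_lte(kr$metastability, 0.5)
})

test_that("a common phase rotation leaves R(t) unchanged", {
  TR <- 2
  set.seed(16)
  m <- t(replicate(5, narrowband_test_signal(300, TR)))
  fb <- bandpass(m, TR_s = TR)
  shift <- function(x, th) Re(analytic_signal(x) * exp(1i * th))
  fb2 <- t(apply(fb, 1, shift, th = 1.1))
  # finite-window analytic-signal leakage keeps this from being exact
  expect_equal(kuramoto(fb)$R_t, kuramoto(fb2)$R_t, tolerance = 0.02)
})

test_that("compute_metrics assembles a consistent report and flat row", {
  set.seed(17)
  m <- t(replicate(10, narrowband_test_signal(150, 2) + rnorm(150, 0, 2)))
  part <- synth_partition(10, seed = 4)
  rep <- compute_metrics(m, part = part, TR_s = 2)
  expect_true(all(abs(rep$FC) <= 1 + 1e-12))
  expect_true(rep$mean_R >= 0 && rep$mean_R <= 1)
  expect_gte(rep$metastability, 0)
  row <- metrics_row(rep)
  expect_equal(row$gbc_global, rep$gbc_global)
  expect_true(all(c("gbc_association", "gbc_sensory", "mean_R",
                    "metastability") %in% names(row)))
})
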