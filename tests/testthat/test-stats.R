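test_that("summary t test: null identity, demographics example, moment-matched oracle", {
  z <- ttest_from_summary(5, 2, 20, 5, 2, 20)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  # age comparison from the demographic table reproduces |t| = 0.82
  tb <- ttest_from_summary(36.70, 11.04, 43, 38.97, 13.67, 38, "welch")
  expect_equal(round(abs(tb$t), 2), 0.82)
  expect_gt(tb$p, 0.4)
  # oracle: construct samples with exactly the requested moments
  set.seed(21)
  for (rep in 1:5) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    mk <- function(n, m, s) {
      z <- rnorm(n); z <- (z - mean(z)) / sd(z)
      m + s * z
    }
    x <- mk(n1, m1, s1); y <- mk(n2, m2, s2)
    for (variant in c("welch", "pooled")) {
      ref <- t.test(x, y, var.equal = (variant == "pooled"))
      got <- ttest_from_summary(m1, s1, n1, m2, s2, n2, variant)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("2x2 chi-square matches the expected-count formula oracle", {
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$p, 1)
  expect_equal(chi_square_2x2(matrix(c(20, 10, 40, 20), 2))$chi2, 0)
  set.seed(22)
  for (rep in 1:5) {
    tab <- matrix(sample(5:40, 4, replace = TRUE), 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    for (cc in c(FALSE, TRUE)) {
      adj <- if (cc) pmax(0, abs(tab - E) - 0.5) else abs(tab - E)
      chi_ora <- sum(adj^2 / E)
      got <- chi_square_2x2(tab, continuity = cc)
      expect_equal(got$chi2, chi_ora, tolerance = 1e-10)
    }
  }
})

test_that("Hedges' g: null, bias-correction direction, formula oracle, antisymmetry", {
  x <- rnorm(10)
  expect_equal(hedges_g(x, x)$g, 0)
  # two samples exactly one pooled SD apart: g = J * 1 < 1
  set.seed(23)
  z <- rnorm(200); z <- (z - mean(z)) / sd(z)
  hg <- hedges_g(z + 1, z)
  expect_equal(hg$g, hg$J)
  expect_lt(hg$g, 1)
  for (rep in 1:5) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0.5)
    n1 <- length(a); n2 <- length(b); df <- n1 + n2 - 2
    sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df)
    ora <- (1 - 3 / (4 * df - 1)) * (mean(a) - mean(b)) / sp
    got <- hedges_g(a, b)
    expect_equal(got$g, ora, tolerance = 1e-10)
    expect_equal(got$g, -hedges_g(b, a)$g, tolerance = 1e-12)
    expect_true(got$ci95[1] <= got$g && got$g <= got$ci95[2])
  }
})

test_that("permutation test: extreme-separation floor and exhaustive enumeration", {
  x <- rnorm(30) + 100
  y <- rnorm(30)
  pt <- permutation_test(x, y, n_perm = 500, seed = 3)
  expect_equal(pt$method, "sampled")
  expect_equal(pt$p, 1 / 501)
  # n1 = n2 = 4: all 70 label splits enumerated, against a combn oracle
  set.seed(24)
  a <- rnorm(4); b <- rnorm(4, 1)
  pt2 <- permutation_test(a, b, n_perm = 5000)
  expect_equal(pt2$method, "exhaustive")
  expect_equal(pt2$n_perm, 70)
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  cnt <- sum(apply(utils::combn(8, 4), 2, function(ii)
    abs(mean(pool[ii]) - mean(pool[-ii])) >= obs - 1e-12))
  expect_equal(pt2$p, cnt / 70)
  expect_error(permutation_test(numeric(0), y), "non-empty")
})

test_that("permutation p on standardised data is invariant to a common affine map", {
  set.seed(25)
  x <- rnorm(12); y <- rnorm(12, 0.8)
  sda <- function(v, all) (v - mean(all)) / sd(all)
  p1 <- permutation_test(sda(x, c(x, y)), sda(y, c(x, y)), n_perm = 200,
                         seed = 9)$p
  xa <- 3 * x + 7; ya <- 3 * y + 7
  p2 <- permutation_test(sda(xa, c(xa, ya)), sda(ya, c(xa, ya)),
                         n_perm = 200, seed = 9)$p
  expect_equal(p1, p2)
})

test_that("paired sign-flip test enumerates all sign patterns for small n", {
  d <- c(0.3, 0.25, 0.4, 0.1, 0.05, 0.2, 0.15, 0.35)
  pt <- paired_signflip_test(d)
  expect_equal(pt$method, "exhaustive")
  expect_equal(pt$n_perm, 256)
  expect_equal(pt$p, 2 / 256)  # all-positive differences: only +/- full flips
  d2 <- c(d, -0.01)
  expect_lt(paired_signflip_test(d2)$p, 0.05)
})

test_that("group_comparison mirrors its ingredient statistics", {
  set.seed(26)
  x <- rnorm(15, 1); y <- rnorm(12)
  gc <- group_comparison(x, y, measure = "demo", n_perm = 200, seed = 5)
  expect_equal(gc$mean_difference, mean(x) - mean(y))
  expect_equal(gc$hedges_g, hedges_g(x, y)$g)
  expect_equal(gc$p_value, permutation_test(x, y, n_perm = 200, seed = 5)$p)
  expect_true(gc$ci95_low <= gc$hedges_g & gc$hedges_g <= gc$ci95_high)
  gc0 <- group_comparison(y, y, n_perm = 100)
  expect_equal(gc0$mean_difference, 0)
  expect_equal(gc0$hedges_g, 0)
})
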