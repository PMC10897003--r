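test_that("synthetic connectomes satisfy every structural invariant and are pure in the seed", {
  for (seed in c(1, 7, 19)) {
    sc <- synth_connectome(n_regions = 30, seed = seed)
    C <- sc$conn$C
    expect_true(isSymmetric(C))
    expect_true(all(diag(C) == 0))
    expect_true(all(C >= 0))
    expect_equal(max(C), 1)
    expect_true(isSymmetric(sc$lengths_mm))
    expect_equal(sc$conn$D, sc$lengths_mm / 20, tolerance = 1e-12)
  }
  a <- synth_connectome(n_regions = 30, seed = 5)
  b <- synth_connectome(n_regions = 30, seed = 5)
  expect_identical(a$conn$C, b$conn$C)
})

test_that("with full density and no jitter, weights decrease with distance", {
  sc <- synth_connectome(n_regions = 25, seed = 2, density = 1,
                         jitter_sdlog = 0)
  ut <- upper.tri(sc$conn$C)
  ord <- order(sc$lengths_mm[ut])
  w <- sc$conn$C[ut][ord]
  expect_true(all(diff(w) <= 1e-12))
})

test_that("synthetic partitions cover all seven networks with imbalance", {
  for (seed in c(1, 3)) {
    part <- synth_partition(40, seed = seed)
    expect_s3_class(part, "aln_partition")
    expect_length(part$network, 40)
    expect_setequal(unique(part$network),
                    c("SomMot", "Cont", "Def", "Sal/VAttn", "DAttn",
                      "Lim", "Vis"))
  }
  expect_identical(synth_partition(40, 9)$network,
                   synth_partition(40, 9)$network)
  f <- tempfile(fileext = ".tsv")
  part <- synth_partition(15, 2)
  write_partition(part, f)
  expect_identical(read_partition(f)$network, part$network)
})

test_that("perfect common drive gives FC, GBC and synchrony of one", {
  g <- synth_bold_groups(n_controls = 3, n_patients = 2, n_regions = 12,
                         T_volumes = 80, gbc_effect = 0, sync_effect = 0,
                         gbc_mean = 1, gbc_sd = 0, seed = 4)
  rep <- compute_metrics(g$controls[[1]])
  expect_gt(min(rep$FC), 0.999)
  expect_gt(rep$gbc_global, 0.999)
  expect_gt(rep$mean_R, 0.99)
})

test_that("generated groups impose the connectivity reduction and are seed-pure", {
  g1 <- synth_bold_groups(n_controls = 6, n_patients = 6, n_regions = 20,
                          T_volumes = 100, seed = 8)
  g2 <- synth_bold_groups(n_controls = 6, n_patients = 6, n_regions = 20,
                          T_volumes = 100, seed = 8)
  expect_identical(g1$controls[[3]]$bold, g2$controls[[3]]$bold)
  expect_equal(nrow(g1$subject_table), 12)
  gc <- mean(sapply(g1$controls, function(b) compute_metrics(b)$gbc_global))
  gp <- mean(sapply(g1$patients, function(b) compute_metrics(b)$gbc_global))
  expect_gt(gc, gp)  # imposed direction at the default effect size
})

test_that("null groups are exchangeable: permutation rejection rate is about alpha", {
  nrep <- 200
  rej <- withr::with_seed(31, {
    sapply(seq_len(nrep), function(k) {
      g <- synth_bold_groups(n_controls = 8, n_patients = 8,
                             n_regions = 15, T_volumes = 60,
                             gbc_effect = 0, sync_effect = 0,
                             seed = 1000 + k)
      gx <- sapply(g$controls, function(b) compute_metrics(b)$gbc_global)
      gy <- sapply(g$patients, function(b) compute_metrics(b)$gbc_global)
      permutation_test(gx, gy, n_perm = 99, seed = k)$p <= 0.05
    })
  })
  rate <- mean(rej)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / nrep)
  expect_gte(rate, ci[1] - 1e-9)
  expect_lte(rate, ci[2] + 1e-9)
})

test_that("motion tables and the exclusion filter behave as specified", {
  mt <- synth_motion_table(10, 8, seed = 6)
  expect_equal(nrow(mt), 18)
  expect_true(all(mt$fd > 0))
  expect_identical(synth_motion_table(10, 8, seed = 6)$fd, mt$fd)
  expect_equal(nrow(apply_motion_filter(mt, Inf)), 18)
  expect_error(apply_motion_filter(mt, 0), "excludes every subject")
  # crafted table with known exceedances
  crafted <- tibble::tibble(
    subject = sprintf("s%d", 1:6),
    group = rep(c("control", "patient"), each = 3),
    fd = c(0.1, 0.35, 0.2, 0.31, 0.15, 0.29))
  kept <- apply_motion_filter(crafted, 0.3)
  expect_setequal(kept$subject, c("s1", "s3", "s5", "s6"))
})
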