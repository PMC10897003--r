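#' Two-sample t test from summary statistics
#'
#' @param m1,sd1,n1 Mean, standard deviation and size of group 1.
#' @param m2,sd2,n2 Mean, standard deviation and size of group 2.
#' @param variant `"welch"` (unequal variances, Welch-Satterthwaite df) or
#'   `"pooled"` (classical Student).
#' @return List with `t`, `df` and two-sided `p`.
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                               variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (variant == "welch") {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test for a 2 x 2 table
#'
#' @param tab 2 x 2 contingency table (counts).
#' @param continuity Apply the Yates continuity correction?
#' @return List with `chi2` and `p`.
#' @export
chi_square_2x2 <- function(tab, continuity = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  res <- suppressWarnings(chisq.test(tab, correct = continuity))
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}

#' Hedges' g with 95 % confidence interval
#'
#' Small-sample bias-corrected standardised mean difference
#' `g = J(df) * (mean(x) - mean(y)) / s_pooled` with
#' `J(df) = 1 - 3 / (4 df - 1)`, `df = n1 + n2 - 2`.  The confidence
#' interval uses the normal approximation to the sampling variance
#' `(n1 + n2)/(n1 n2) + g^2 / (2 (n1 + n2 - 2))`.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @return List with `g`, `ci95` (length-2 vector), `J`, `df`.
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need at least two observations")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df)
  J <- 1 - 3 / (4 * df - 1)
  g <- if (sp == 0) 0 else J * (mean(x) - mean(y)) / sp
  vg <- (n1 + n2) / (n1 * n2) + g^2 / (2 * df)
  ci <- g + c(-1, 1) * qnorm(0.975) * sqrt(vg)
  list(g = g, ci95 = ci, J = J, df = df)
}

#' Two-sided label permutation test
#'
#' The p value is the proportion of label permutations whose absolute
#' statistic is at least the observed one, counting the identity
#' permutation in numerator and denominator.  When all distinct label
#' splits number at most `n_perm` the test enumerates them exhaustively;
#' otherwise it samples `n_perm` random permutations.
#'
#' @param x,y Numeric samples.
#' @param statistic Function of `(x, y)`; default difference of means.
#' @param n_perm Number of permutations (paper default 5000).
#' @param seed Seed for the sampled variant.
#' @return List with `p`, `observed`, `n_perm`, `method`
#'   (`"exhaustive"` or `"sampled"`).
#' @export
permutation_test <- function(x, y,
                             statistic = function(x, y) mean(x) - mean(y),
                             n_perm = 5000, seed = 1) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pool <- c(x, y)
  n <- n1 + n2
  obs <- abs(statistic(x, y))
  n_splits <- choose(n, n1)
  if (n_splits <= n_perm) {
    idx <- utils::combn(n, n1)
    stats <- apply(idx, 2, function(ii)
      abs(statistic(pool[ii], pool[-ii])))
    p <- sum(stats >= obs - 1e-12) / ncol(idx)
    return(list(p = p, observed = obs, n_perm = ncol(idx),
                method = "exhaustive"))
  }
  count <- withr::with_seed(as.integer(seed), {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      ii <- sample.int(n, n1)
      if (abs(statistic(pool[ii], pool[-ii])) >= obs - 1e-12) {
        hits <- hits + 1L
      }
    }
    hits
  })
  # identity permutation counted in numerator and denominator
  list(p = (count + 1L) / (n_perm + 1L), observed = obs, n_perm = n_perm,
       method = "sampled")
}

#' Paired sign-flip permutation test
#'
#' For measures compared across conditions that share the same virtual
#' subjects (fixed noise seeds), the natural unit is the within-subject
#' difference; under the null the sign of each difference is exchangeable.
#' The statistic is the mean difference; all `2^n` sign assignments are
#' enumerated when feasible, otherwise sampled.
#'
#' @param d Vector of paired differences.
#' @param n_perm Maximum number of sign patterns before sampling.
#' @param seed Seed for the sampled variant.
#' @return List with two-sided `p`, `observed`, `n_perm`, `method`.
#' @export
paired_signflip_test <- function(d, n_perm = 5000, seed = 1) {
  n <- length(d)
  if (n < 2) stop("need at least two paired differences")
  obs <- abs(mean(d))
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- abs(signs %*% d) / n
    p <- sum(stats >= obs - 1e-12) / nrow(signs)
    return(list(p = p, observed = mean(d), n_perm = nrow(signs),
                method = "exhaustive"))
  }
  count <- withr::with_seed(as.integer(seed), {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      sg <- sample(c(-1, 1), n, replace = TRUE)
      if (abs(mean(sg * d)) >= obs - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(p = (count + 1L) / (n_perm + 1L), observed = mean(d),
       n_perm = n_perm, method = "sampled")
}

#' One group-comparison row (difference, effect size, p)
#'
#' Combines the mean difference, Hedges' g with confidence interval and a
#' permutation (or parametric) p value for one measure, mirroring one row
#' of the group-comparison tables.
#'
#' @param x,y Numeric samples (x = first-named group).
#' @param measure Name of the measure.
#' @param method `"permutation"` or `"parametric"` (Welch).
#' @param n_perm,seed Permutation settings.
#' @return One-row tibble of class `group_comparison`.
#' @export
group_comparison <- function(x, y, measure = "measure",
                             method = c("permutation", "parametric"),
                             n_perm = 5000, seed = 1) {
  method <- match.arg(method)
  hg <- hedges_g(x, y)
  p <- if (method == "permutation") {
    permutation_test(x, y, n_perm = n_perm, seed = seed)$p
  } else {
    ttest_from_summary(mean(x), sd(x), length(x),
                       mean(y), sd(y), length(y))$p
  }
  out <- tibble::tibble(measure = measure,
                        mean_difference = mean(x) - mean(y),
                        hedges_g = hg$g, ci95_low = hg$ci95[1],
                        ci95_high = hg$ci95[2], p_value = p,
                        method = method, n1 = length(x), n2 = length(y),
                        n_permutations = if (method == "permutation")
                          n_perm else NA_integer_,
                        seed = seed)
  class(out) <- c("group_comparison", class(out))
  out
}
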