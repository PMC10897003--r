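#' Perturbation families and their study ranges
#'
#' The four families of model changes examined over virtual-subject
#' cohorts: joint reduction of the inhibitory weights (`gaba_weights`
#' scales J_EI and J_II), reduction of the excitatory drive onto the
#' inhibitory population (`glut_drive_to_I` scales J_IE), reduction of the
#' global coupling (`global_coupling` scales K_gl), and an increase of the
#' background noise (`noise_level` scales sigma_ou).  The study ranges are
#' 100 % down to 60 % in steps of 5 % for the first three and 100 % up to
#' 140 % for the noise family; the reference scale 1 is always included.
#'
#' @param family One of `"gaba_weights"`, `"glut_drive_to_I"`,
#'   `"global_coupling"`, `"noise_level"`.
#' @param scales Numeric scale factors (fractions of the default value).
#' @param allow_out_of_range Permit scales outside the study range.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(family = c("gaba_weights", "glut_drive_to_I",
                                         "global_coupling", "noise_level"),
                              scales = NULL,
                              allow_out_of_range = FALSE) {
  family <- match.arg(family)
  rng <- if (family == "noise_level") c(1, 1.4) else c(0.6, 1)
  if (is.null(scales)) {
    scales <- if (family == "noise_level") seq(1, 1.4, by = 0.05) else
      seq(1, 0.6, by = -0.05)
  }
  if (!allow_out_of_range &&
      any(scales < rng[1] - 1e-9 | scales > rng[2] + 1e-9)) {
    stop(sprintf("scale(s) outside the study range [%g, %g] for '%s'",
                 rng[1], rng[2], family))
  }
  if (!any(abs(scales - 1) < 1e-12)) scales <- c(1, scales)
  structure(list(family = family, scales = scales, range = rng),
            class = "perturbation_spec")
}

#' Apply one perturbation multiplicatively
#'
#' @param pop A [population_params()] object.
#' @param glob A [global_params()] object.
#' @param family Perturbation family (see [perturbation_spec()]).
#' @param scale Multiplicative scale factor.
#' @return List with the modified `pop` and `glob`.
#' @export
apply_perturbation <- function(pop, glob, family, scale) {
  switch(family,
    none = NULL,
    gaba_weights = {
      pop$J_EI <- pop$J_EI * scale
      pop$J_II <- pop$J_II * scale
    },
    glut_drive_to_I = pop$J_IE <- pop$J_IE * scale,
    global_coupling = glob$K_gl <- glob$K_gl * scale,
    noise_level = glob$sigma_ou <- glob$sigma_ou * scale,
    stop("unknown perturbation family: ", family))
  list(pop = pop, glob = glob)
}

#' A fixed cohort of virtual subjects
#'
#' One virtual subject is one master noise seed; the seed list is created
#' once and reused unchanged for every model condition so that conditions
#' can be compared subject-by-subject.
#'
#' @param conn An [connectome()] object (shared by all subjects).
#' @param pop,glob Default parameters.
#' @param tables Transfer tables.
#' @param part Optional [partition()] for sub-network measures.
#' @param n_subjects Cohort size (study default 40).
#' @param seed_base First master seed; subject k uses `seed_base + k - 1`.
#' @param TR BOLD repetition time (s).
#' @param hemo A [hemo_params()] object.
#' @return An object of class `virtual_cohort`.
#' @export
virtual_cohort <- function(conn, pop, glob, tables, part = NULL,
                           n_subjects = 40, seed_base = 1, TR = 2,
                           hemo = hemo_params()) {
  stopifnot(n_subjects >= 1)
  structure(list(conn = conn, pop = pop, glob = glob, tables = tables,
                 part = part, seeds = seed_base + seq_len(n_subjects) - 1L,
                 TR = TR, hemo = hemo),
            class = "virtual_cohort")
}

#' Run one model condition over a cohort
#'
#' For every subject seed: simulate the network, convert the excitatory
#' rates to BOLD, and compute the connectivity/dynamics measures.  The
#' scale is applied multiplicatively to the family's parameter(s) only;
#' `scale = 1` reproduces the default condition bit-identically.
#'
#' @param cohort A [virtual_cohort()] object.
#' @param family Perturbation family or `"none"`.
#' @param scale Scale factor.
#' @param allow_out_of_range Permit scales outside the study range.
#' @return List with `measures` (tibble, one row per subject incl. the
#'   seed), `reports` (list of `metrics_report`), `family`, `scale`.
#' @export
run_condition <- function(cohort, family = "none", scale = 1,
                          allow_out_of_range = FALSE) {
  stopifnot(inherits(cohort, "virtual_cohort"))
  if (family != "none") {
    spec <- perturbation_spec(family, scales = scale,
                              allow_out_of_range = allow_out_of_range)
    stopifnot(scale %in% spec$scales)
  }
  pg <- apply_perturbation(cohort$pop, cohort$glob, family, scale)
  reports <- vector("list", length(cohort$seeds))
  rows <- vector("list", length(cohort$seeds))
  for (k in seq_along(cohort$seeds)) {
    seed <- cohort$seeds[k]
    sim <- tryCatch(
      simulate_network(cohort$conn, pg$pop, pg$glob, cohort$tables, seed),
      error = function(e) stop(sprintf(
        "condition %s@%g failed for seed %d: %s", family, scale, seed,
        conditionMessage(e)), call. = FALSE))
    bold <- bold_from_rates(sim, params = cohort$hemo, TR_s = cohort$TR)
    rep <- compute_metrics(bold, part = cohort$part)
    reports[[k]] <- rep
    rows[[k]] <- cbind(tibble::tibble(seed = seed), metrics_row(rep))
  }
  list(measures = do.call(rbind, rows), reports = reports,
       family = family, scale = scale)
}

#' Compare a perturbed condition with the default condition
#'
#' Produces one row per measure in the shape of the perturbation tables.
#' Because the sign convention of the printed tables is internally
#' inconsistent, both differences are emitted explicitly:
#' `diff_default_minus_condition` and `diff_condition_minus_default`.
#' Hedges' g is reported for condition minus default (negative when the
#' perturbed condition is lower).  Two p values are attached: the label
#' permutation test over the two groups of subjects (the published
#' convention) and a sign-flip permutation over the within-subject (same
#' seed) differences, which is the sharper test for a cohort that is held
#' fixed across conditions.
#'
#' @param default_cond,cond Results from [run_condition()] (or bare
#'   measure tibbles with a `seed` column).
#' @param measures Character vector of measure columns to compare.
#' @param n_perm Number of permutations.
#' @param seed Seed for sampled permutations.
#' @return A tibble of class `condition_comparison`.
#' @export
compare_to_default <- function(default_cond, cond,
                               measures = c("gbc_global", "gbc_sensory",
                                            "gbc_association", "mean_R",
                                            "metastability"),
                               n_perm = 5000, seed = 1) {
  md <- if (is.list(default_cond) && !is.data.frame(default_cond))
    default_cond$measures else default_cond
  mc <- if (is.list(cond) && !is.data.frame(cond)) cond$measures else cond
  stopifnot(all(measures %in% names(md)), all(measures %in% names(mc)))
  if (!identical(md$seed, mc$seed)) {
    stop("conditions must share the same subject seeds, in the same order")
  }
  rows <- lapply(measures, function(ms) {
    x <- mc[[ms]]  # condition
    y <- md[[ms]]  # default
    hg <- hedges_g(x, y)
    pt_lab <- permutation_test(x, y, n_perm = n_perm, seed = seed)
    pt_pair <- paired_signflip_test(x - y, n_perm = n_perm, seed = seed)
    tibble::tibble(measure = ms,
                   mean_default = mean(y), mean_condition = mean(x),
                   diff_default_minus_condition = mean(y) - mean(x),
                   diff_condition_minus_default = mean(x) - mean(y),
                   hedges_g = hg$g, abs_g = abs(hg$g),
                   ci95_low = hg$ci95[1], ci95_high = hg$ci95[2],
                   p_permutation = pt_lab$p, p_paired = pt_pair$p,
                   n_subjects = length(x), n_permutations = pt_lab$n_perm)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condition_comparison", class(out))
  out
}

#' Run a full perturbation experiment (one family, several scales)
#'
#' @param cohort A [virtual_cohort()] object.
#' @param family Perturbation family.
#' @param scales Scale factors (defaults to the study range).
#' @param n_perm,seed Permutation settings for the comparisons.
#' @param measures Measures to compare.
#' @return List with `comparisons` (tibble over scales x measures),
#'   `conditions` (list of [run_condition()] results keyed by scale) and
#'   `default` (the scale-1 condition).
#' @export
run_experiment <- function(cohort, family, scales = NULL, n_perm = 5000,
                           seed = 1,
                           measures = c("gbc_global", "gbc_sensory",
                                        "gbc_association", "mean_R",
                                        "metastability")) {
  spec <- perturbation_spec(family, scales)
  default_cond <- run_condition(cohort, "none", 1)
  conds <- list()
  comp <- list()
  for (sc in spec$scales) {
    if (abs(sc - 1) < 1e-12) next
    cc <- run_condition(cohort, family, sc)
    conds[[sprintf("%g", sc)]] <- cc
    tab <- compare_to_default(default_cond, cc, measures = measures,
                              n_perm = n_perm, seed = seed)
    tab <- cbind(tibble::tibble(family = family, scale = sc), tab)
    comp[[sprintf("%g", sc)]] <- tab
  }
  list(comparisons = do.call(rbind, comp), conditions = conds,
       default = default_cond, family = family)
}
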