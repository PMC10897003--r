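#!/usr/bin/env Rscript
# The four model perturbation families over a fixed virtual cohort, in the
# shape of the perturbation tables: one row per scale and measure with both
# sign conventions, Hedges' g and permutation p values.  Cohort size and
# scale grid are reduced relative to the full study (40 subjects, 9 scales)
# to keep this driver interactive; the acceptance suite runs the denser
# contrasts.

library(alnsim)
dir.create("results", showWarnings = FALSE)

tables <- read_transfer_tables("results/transfer_tables.rds")
sc <- synth_connectome(80, seed = 1)
part <- synth_partition(80, seed = 1)
cohort <- virtual_cohort(sc$conn, population_params(), global_params(),
                         tables, part, n_subjects = 6, seed_base = 101,
                         TR = 2)

fams <- list(global_coupling = c(0.9, 0.8),
             noise_level = c(1.1, 1.2),
             gaba_weights = c(0.8),
             glut_drive_to_I = c(0.8))
for (fam in names(fams)) {
  ex <- run_experiment(cohort, fam, scales = c(1, fams[[fam]]),
                       n_perm = 2000, seed = 1)
  f <- sprintf("results/perturbation_%s.tsv", fam)
  write.table(format(ex$comparisons, digits = 4), f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat("\n==", fam, "\n")
  print(as.data.frame(ex$comparisons)[, c("scale", "measure",
        "diff_default_minus_condition", "hedges_g", "p_permutation",
        "p_paired")], digits = 3)
}
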