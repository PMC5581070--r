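#!/usr/bin/env Rscript
# The statistical battery on the simulated cohort: univariate screens for
# EGFR and KRAS, and the multivariate logistic model (gender, smoking,
# SUVmax, 1/COV).

suppressPackageStartupMessages(library(pethet))
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(cohort_spec(seed = 1L))

for (gene in c("egfr", "kras")) {
  sc <- univariate_scan(cohort, gene)
  write.csv(sc, sprintf("results/03_univariate_%s.csv", gene),
            row.names = FALSE)
  cat("\nUnivariate screen,", toupper(gene), "(score-test / chi-square p):\n")
  print(sc[, c("index", "n_pos", "n_neg", "p_mw", "p")], row.names = FALSE,
        digits = 3)
}

fit <- suppressWarnings(multivariate_logistic(cohort, "egfr"))
write.csv(fit, "results/03_multivariate_egfr.csv", row.names = FALSE)
cat("\nMultivariate logistic model for EGFR (n =", attr(fit, "n"), "):\n")
print(fit, row.names = FALSE, digits = 3)
cat("\nAt this sample size the never-smoker term dominates;",
    "\nSUVmax and 1/COV, associated univariately through the smoking",
    "\nconfounder, are not significant conditionally.\n")
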