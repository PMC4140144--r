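#!/usr/bin/env Rscript
# Correlation analysis and downselection: Pearson matrix of the screened
# variables against the RC code and each other, then the greedy
# low-collinearity rule (|r| with dose >= 0.25, mutual |r| <= 0.67, time
# always retained). Writes results/correlation_matrix.csv + selection.csv.

suppressPackageStartupMessages(library(bloodrc))

cohort <- read_cohort("results/cohort.csv")
scr <- readr::read_csv("results/screening.csv", show_col_types = FALSE)
screened <- scr$variable[scr$passed_radioresponse_filter]

cm <- pearson_matrix(cohort, screened)
write.csv(round(cm$r, 3), "results/correlation_matrix.csv")
cat("correlations with the RC code (dose), strongest first:\n")
r_dose <- sort(cm$r[screened, "dose_code"], decreasing = TRUE)
print(round(r_dose, 2))

sel <- downselect(cm)
readr::write_csv(sel, "results/selection.csv")
cat("\ndownselection decisions:\n")
print(as.data.frame(sel), digits = 3, row.names = FALSE)
cat("\nselected predictors:",
    paste(selected_predictors(sel), collapse = ", "), "\n")
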