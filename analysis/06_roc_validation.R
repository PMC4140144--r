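#!/usr/bin/env Rscript
# ROC validation: per-day and pooled Mann-Whitney AUC with stratified
# bootstrap 95% confidence limits for each of the seven blood variables, and
# linear-discriminant panel AUCs for the CBC (3-marker) and CBC-SCHEM
# (7-marker) combinations. Writes results/roc_univariate.csv + roc_panels.csv.

suppressPackageStartupMessages({
  library(bloodrc)
  library(dplyr)
  library(tidyr)
})

cohort <- read_cohort("results/cohort.csv")
markers <- names(default_profiles())

tab <- roc_table(cohort, markers, n_boot = 2000, seed = 7)
readr::write_csv(tab, "results/roc_univariate.csv")
cat("univariate AUC by day (rows = marker):\n")
print(as.data.frame(pivot_wider(tab[c("marker", "day", "auc")],
                                names_from = day, values_from = auc)),
      digits = 2, row.names = FALSE)

panels <- list(cbc = c("ALC", "ANC", "APC"), cbc_schem = markers)
days <- sort(unique(cohort$day[cohort$dose_code == 3]))
panel_tbl <- bind_rows(lapply(names(panels), function(nm) {
  per_day <- lapply(days, function(d) {
    r <- auc_panel(cohort, panels[[nm]], day_filter = d)
    tibble::tibble(panel = nm, day = as.character(d), auc = r$auc,
                   method = r$method)
  })
  pooled <- auc_panel(cohort, panels[[nm]])
  bind_rows(per_day, tibble::tibble(panel = nm, day = "pooled",
                                    auc = pooled$auc,
                                    method = pooled$method))
}))
readr::write_csv(panel_tbl, "results/roc_panels.csv")
cat("\npanel AUCs (linear-discriminant combination):\n")
print(as.data.frame(pivot_wider(panel_tbl[c("panel", "day", "auc")],
                                names_from = day, values_from = auc)),
      digits = 2, row.names = FALSE)
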