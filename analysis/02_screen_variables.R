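#!/usr/bin/env Rscript
# Candidate-variable identification: the <=10% SEM precision filter followed
# by the >=10% radioresponse filter, applied to every blood variable in the
# cohort. Writes results/screening.csv.

suppressPackageStartupMessages({
  library(bloodrc)
  library(dplyr)
})

cohort <- read_cohort("results/cohort.csv")
vars <- setdiff(names(cohort), c("animal_id", "cohort", "day", "dose_code"))

scr <- screen_panel(cohort, vars)
flat <- select(scr, -irradiated_mean_by_day, -percent_difference_by_day) |>
  mutate(mean_abs_pct_diff = vapply(scr$percent_difference_by_day, mean, 0))
readr::write_csv(flat, "results/screening.csv")

cat("screening results:\n")
print(as.data.frame(flat[c("variable", "control_mean", "control_sem",
                           "mean_abs_pct_diff", "sem_of_percent_differences",
                           "passed_sem_filter",
                           "passed_radioresponse_filter")]),
      digits = 3, row.names = FALSE)
cat(sprintf("\n%d of %d variables pass both filters: %s\n",
            sum(flat$passed_radioresponse_filter), nrow(flat),
            paste(flat$variable[flat$passed_radioresponse_filter],
                  collapse = ", ")))
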