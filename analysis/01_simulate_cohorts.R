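#!/usr/bin/env Rscript
# Stage 1: generate the four reference cohorts (task and symptom subscales
# in a well-targeted CTS-like population and a mistargeted, negatively
# skewed Dupuytren-like population) and write them as questionnaire-coded
# CSVs for the later stages.

suppressPackageStartupMessages(library(raschdash))
dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)

seed <- 20240201L
for (name in c("cts_tasks", "dupuytren_tasks",
               "cts_symptoms", "dupuytren_symptoms")) {
  m <- simulate_responses(cohort_spec(name, seed = seed))
  path <- file.path("results/cohorts", paste0(name, ".csv"))
  write_responses(m, path)
  cat(sprintf("%-20s n = %4d, items: %s\n", name, nrow(m$values),
              paste(m$item_ids, collapse = " ")))
}
cat("cohorts written under results/cohorts/\n")
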