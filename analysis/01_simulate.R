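#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort (154 cases, default
# parameters) and write its tables plus the planted truth under results/.
suppressPackageStartupMessages(library(socs1mut))

dir.create("results", showWarnings = FALSE)
model <- socs1_model()
cohort <- generate_cohort(sim_params(seed = 20240101L), model)
paths <- write_cohort(cohort, file.path("results", "cohort"))
cat("cohort written:\n"); print(paths)
cat(sprintf("cases: %d, mutated: %d, mutation records: %d\n",
            nrow(cohort$clinical), length(unique(cohort$mutations$case_id)),
            nrow(cohort$mutations)))
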