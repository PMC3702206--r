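#!/usr/bin/env Rscript
# Step 3: call the major / minor / wild-type subtype per case and write the
# severity-sorted case list.
suppressPackageStartupMessages(library(socs1mut))

model <- socs1_model()
mutations <- read_mutation_table(file.path("results", "cohort", "mutations.tsv"),
                                 model)
clinical <- read_clinical_table(file.path("results", "cohort", "clinical.tsv"))

calls <- classify_cohort(mutations, model, case_ids = clinical$case_id)
ccs <- cohort_consequences(mutations, model,
                           case_ids = unique(mutations$case_id))
ord <- severity_sort(ccs)
merged <- merge(ord, calls, by = "case_id", sort = FALSE)

out <- file.path("results", "subtypes.tsv")
write.table(merged, out, sep = "\t", quote = FALSE, row.names = FALSE)
cat("subtype calls ->", out, "\n")
print(table(calls$call))
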