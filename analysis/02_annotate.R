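#!/usr/bin/env Rscript
# Step 2: re-read the simulated mutation table (round-trip through the I/O
# layer), annotate per-mutation effects and per-case consequences, and write
# the annotated tables.
suppressPackageStartupMessages(library(socs1mut))

model <- socs1_model()
mutations <- read_mutation_table(file.path("results", "cohort", "mutations.tsv"),
                                 model)
out <- file.path("results", "consequences.tsv")
write_consequence_table(mutations, model, out)
cat("annotated", nrow(mutations), "mutations ->", out, "\n")

ann <- annotate_mutations(mutations, model)
print(table(ann$effect))
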