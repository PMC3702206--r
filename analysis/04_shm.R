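#!/usr/bin/env Rscript
# Step 4: hypermutation-motif targeting — per-family summary of point
# mutations at mutable motif positions and the permutation enrichment test.
suppressPackageStartupMessages(library(socs1mut))

model <- socs1_model()
mutations <- read_mutation_table(file.path("results", "cohort", "mutations.tsv"),
                                 model)

s <- summarize_shm(mutations, model)
enr <- shm_enrichment_test(mutations, model, B = 5000, seed = 20240104L)
res <- c(s[c("n_point", "n_at_motif", "fraction", "n_gc", "n_gc_at_motif",
             "n_at", "n_at_at_motif")],
         list(enrichment_p = enr$p, background_density = enr$background_density,
              B = enr$B))
out <- file.path("results", "shm_summary.json")
jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("hypermutation summary ->", out, "\n")
cat(sprintf("at-motif fraction: %.3f (background %.3f), permutation p = %.4g\n",
            s$fraction, enr$background_density, enr$p))
print(s$per_family)
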