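#!/usr/bin/env Rscript
# Step 5: published-table associations — recompute the mutant-case tallies
# and the mutant-status vs expression-signature exact tests from the
# machine-transcribed fixture tables.
suppressPackageStartupMessages(library(socs1mut))

cases <- socs1_mutant_cases()
counts <- socs1_cohort_counts()

tallies <- do.call(rbind, lapply(c("cd10", "bcl2", "bcl6", "mum1",
                                   "bcl6_fish", "myc_fish"), function(mk) {
  t <- marker_tally(cases, mk)
  data.frame(marker = mk, n_positive = t$n_positive,
             n_evaluable = t$n_evaluable, percent = round(t$percent, 1))
}))

tests <- do.call(rbind, lapply(c("coo", "mbl", "pap", "cc"), function(sig) {
  tab <- t(signature_status_table(sig))
  res <- fisher_exact_rxc(tab)
  data.frame(signature = sig, levels = nrow(tab), n = sum(tab),
             p = res$p, method = res$method)
}))
pap1 <- fisher_exact_2x2(signature_status_table("pap", collapse = "PAP-1"))

write.table(tallies, file.path("results", "marker_tallies.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tests, file.path("results", "signature_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mutant prevalence: %d/%d (%.0f%%)\n", counts$n_mutant,
            counts$n_total, 100 * counts$n_mutant / counts$n_total))
print(tallies); print(tests)
cat(sprintf("mutant x PAP-1 (2x2) exact p = %.4g\n", pap1))
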