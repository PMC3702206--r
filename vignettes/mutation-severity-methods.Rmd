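---
title: "Methods: single-gene mutation-severity subtyping and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-gene mutation-severity subtyping and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model and the numerical procedures implemented by
`socs1mut`. The package analyzes coding mutations of a single gene against a
domain-annotated gene model, calls a case-level severity subtype, quantifies
somatic-hypermutation (SHM) motif targeting, and runs the cohort-level
association and survival statistics. SOCS1 in diffuse large B-cell lymphoma
(DLBCL) is the packaged default: SOCS1 is intronless with a 636-nt coding
sequence whose C-terminal nuclear localization signal (NLS) and SOCS box are
the functionally critical domains, and it is a frequent target of aberrant
somatic hypermutation.

## The gene model

A `gene_model()` bundles a coding sequence (CDS, validated to start with ATG,
end with a stop, and contain no internal in-frame stop), a codon-addressed
domain table (with an `is_cterminal` flag marking the domains whose loss
defines the severe subtype), optional flanking context sequence for
motif scanning at the CDS edges, and the CDS offset within the
transcript/exon (`cds_offset_in_exon2`, default 705 to mirror the SOCS1
exon-2 coordinates; position `c.636` then maps to transcript position 1340).
`transcript_to_cds_position()` and `cds_to_transcript_position()` convert
between the two frames, and `find_amplicon()` performs printed-primer
arithmetic (forward match plus reverse-complement match; the packaged
synthetic template yields the expected 761-bp product).

The packaged model (`socs1_model()`) is a **synthetic stand-in**: the CDS,
flanking contexts, and domain boundaries are generated/plausible rather than
the true human sequence, because the package ships no copyrighted database
sequence. All coordinate arithmetic (636-nt CDS at offset 705, amplicon
geometry) is preserved by construction, so every pipeline step runs
unmodified on a user-supplied real gene model (`load_gene_model()` reads a
JSON + FASTA description).

## Mutation records and per-case consequences

Mutations use HGVS-like c. notation restricted to four kinds: substitution
(`c.123A>G`), deletion (`c.100_102del`), tandem duplication (`c.50_52dup`),
and insertion (`c.70_71insACG`). `read_mutation_table()` validates reference
bases against the model and flags exact duplicate rows; coordinates are
reference-frame and stay valid because events are applied 3'→5'.

Per mutation, `classify_mutation()` assigns silent / missense / nonsense /
frameshift / in-frame classes by codon-table lookup and net-length
arithmetic. Per case, `apply_case_mutations()` merges all events into:

* the mutant CDS (overlapping deletions are rejected as conflicting;
  same-position substitutions apply last-wins with a warning);
* the **intact coding length**: the minimum over `c_start - 1` for each
  frame-disrupting indel, `3*(s-1)` for each stop gain at codon `s`, and the
  full length otherwise. This is the severity axis used for sorting.
  In-frame indels deliberately do *not* bound it — they preserve the
  downstream reading frame, and their effect is captured by the
  domain-weighting schemes instead (see the design notes below);
* three affected-domain sets. **Direct**: an event footprint intersects the
  domain's nucleotide interval. **Conservative** adds only complete loss: the
  whole interval lies beyond the intact length, or a deletion removes it
  entirely. **Aggressive** adds partial loss (any part beyond the intact
  length), partial deletion, and *position shifts* (any net-length-changing
  event 5' of the domain start). Conservative ⊆ aggressive holds by
  construction and is property-tested. Stored sets are the union of direct
  and downstream hits.

## Severity subtype

`classify_case()` calls `wild_type` (no mutations), `major` (at least one
foreshortening event — stop gain, frameshift, any deletion, frame-disrupting
duplication/insertion — whose *per-event* aggressive impact reaches a
C-terminal domain), or `minor` (only non-foreshortening substitutions).
"Presence or position" of the C-terminal domains is operationalized as the
aggressive weighting because position shifts are explicitly part of the
definition. Edge cases that the motivating study never exhibits
(foreshortening events that reach no C-terminal domain, or in-frame indels
only) default to `major` with `ambiguous = TRUE` — a severity-conservative
default rather than a new class. `severity_sort()` orders cases by ascending
intact length, then descending mutation count, then case id.

## Hypermutation motifs

Six motif families are scanned on the forward strand:
RGYW, WRCY, DGYW, WRCH, WA, TW, with mutable offsets 1, 2, 1, 2, 1, 0
(0-based within the motif). Scanning both strands is realized by scanning
all six families forward, because the families form reverse-complement pairs
(RGYW↔WRCY, DGYW↔WRCH, WA↔TW) — a closure property the tests verify
exactly. Matching uses `Biostrings::matchPattern(fixed = FALSE)` for IUPAC
degeneracy; a naive sliding-window oracle re-implements the scan
independently in the test suite. A point mutation is "at a motif" when it
hits the mutable position of some occurrence; positions within 3 nt of a
contextless CDS edge carry a `boundary_uncertain` flag. For deletions,
`deletion_flank_shm()` checks a window (default 4 nt) outside each
breakpoint, since breakpoints of SHM-associated deletions cluster near
hotspot motifs.

`shm_enrichment_test()` is a permutation test: the observed number of
substitutions at mutable positions is compared against `B` uniform
repositionings over the CDS, with `p = (r + 1)/(B + 1)`. The test is exact
in distribution under the uniform null; the acceptance suite checks both its
power at strong targeting and its size at the background mutable density.

## Cohort statistics

* `fisher_exact_2x2()`: own implementation summing hypergeometric
  probabilities `<=` the observed one (relative tolerance `1 + 1e-12`), with
  `stats::fisher.test` used as an independent cross-check in tests only.
* `fisher_exact_rxc()`: Freeman–Halton generalization by recursive
  enumeration of all tables with the observed margins (with a feasibility
  prune so the enumeration is output-linear), log-probability arithmetic,
  and a total-probability conservation check (`sum = 1 ± 1e-9`). Above
  `max_tables` it falls back to a seeded Monte Carlo estimate via
  `stats::r2dtable`.
* `km_fit()` / `cox_fit()` wrap `survival::survfit` / `survival::coxph`
  (Breslow ties by default) — standard, well-tested numerics are wrapped
  rather than re-implemented, while `breslow_loglik()` exposes the partial
  likelihood so tests can verify the fit against a brute-force grid
  maximizer. `cox_fit()` performs complete-case analysis, errors on
  constant covariates, and flags monotone-likelihood/separation fits.
* `encode_covariates()` reproduces the published 0/1 encodings (age>60,
  LDH>ULN, ECOG>1, stage III/IV, >1 extranodal site, B symptoms, IB
  morphology, non-GCB, non-mBL, non-PAP-1, non-BCR, IPI>=2, and the subtype
  dummies), with missingness propagated except in the IPI score, where
  missing components count as absent (the published convention).

## The synthetic cohort generator

Individual-level mutation catalogs and survival times are not published, so
the generator (`generate_cohort()`) emulates the study conditions with
planted truth for end-to-end validation:

* `n_cases = 154`, `mutant_prevalence = 0.16`, even major/minor split —
  matching the reported cohort size and mutant fraction;
* per-mutant mutation counts: truncated geometric on [1, 18] with mean
  about 4 (the reported per-case range);
* substitutions land on mutable motif positions with probability
  `shm_target_prob = 0.41` (the reported at-motif fraction), otherwise on a
  uniformly drawn non-mutable position; major cases additionally receive one
  engineered truncating event (stop gain or 1–2-nt frameshift deletion 5'
  of the C-terminal domains), so the classifier must recover every planted
  call exactly;
* signature labels (COO, mBL, PAP, CC) are drawn from per-subtype
  conditionals proportional to the published per-subtype counts (all major
  cases are GCB under the defaults);
* survival is exponential with baseline hazard 0.02/month and planted log
  hazard ratios (default -1.2 major, +1.0 minor; free parameters, since the
  true individual-level data are unavailable), with uniform censoring whose
  horizon is solved numerically (`uniroot`) to hit the target censoring
  fraction (default 0.3).

Everything is deterministic given `sim_params(seed = ...)`; the generator
saves and restores the global RNG state.

## Numerical and design notes

* The spec-level rule set for the intact length contains an ambiguity:
  applying the `c_start - 1` bound to *all* length-altering events would
  make every in-frame indel pull all downstream domains into the
  conservative set, collapsing the two weighting schemes. The package
  restricts the bound to frame-disrupting events, which keeps the
  documented behavior of the worked example (an in-frame 3-nt deletion
  upstream of the SOCS box affects it under aggressive weighting only).
* Exact duplicate mutation rows are collapsed before merging (one
  biological event reported twice); duplication is flagged at the I/O
  layer.
* The permutation p-value uses the add-one estimator `(r + 1)/(B + 1)`,
  which is valid (never anti-conservative) for any `B`.
* Derived seeds stay below 2^31; all stochastic functions take explicit
  seeds.

## Limitations

* The packaged gene model is synthetic; conclusions about the real SOCS1
  sequence require loading the true CDS and domain coordinates.
* No nonsense-mediated-decay, splice, or protein-stability modeling; the
  severity axis is purely coordinate arithmetic on the CDS.
* The survival component of the generator is a convenience for validating
  the fitting machinery — its hazard ratios are free parameters, not
  estimates of the published effect sizes.
* The Freeman–Halton enumeration is exponential in table size; large tables
  silently use the seeded Monte Carlo path (reported in the `method` field).

## Reproducing the workflow

```{r}
# numbered drivers, run from the repository root after installing the package
# Rscript analysis/01_simulate.R      # synthetic cohort -> results/cohort/
# Rscript analysis/02_annotate.R      # consequences -> results/consequences.tsv
# Rscript analysis/03_subtype.R       # severity calls -> results/subtypes.tsv
# Rscript analysis/04_shm.R           # motif summary  -> results/shm_summary.json
# Rscript analysis/05_associations.R  # published-table tallies and exact tests
# Rscript analysis/06_survival.R      # KM + Cox       -> results/cox_fits.tsv
# and the single-file summary:
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
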