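# Per-mutation effects, intact coding length, mutant sequence construction
# and domain impact under the two weighting schemes.

rec_df <- function(kind, p, q, ref, alt, id = "x") {
  data.frame(case_id = id, kind = kind, c_start = as.integer(p),
             c_end = as.integer(q), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("substitution effects follow the codon table", {
  dom <- data.frame(name = "D", aa_start = 1L, aa_end = 2L, is_cterminal = TRUE)
  m1 <- gene_model("S", "ATGGCTTGA", dom)
  silent <- classify_mutation(rec_df("substitution", 6, 6, "T", "A"), m1)
  expect_equal(silent$effect, "silent")  # GCT -> GCA, both Ala
  m2 <- gene_model("S", "ATGAAATACTGA",
                   data.frame(name = "D", aa_start = 1L, aa_end = 3L,
                              is_cterminal = TRUE))
  non <- classify_mutation(rec_df("substitution", 4, 4, "A", "T"), m2)
  expect_equal(non$effect, "nonsense")  # AAA -> TAA
  expect_equal(non$premature_stop_at, 2L)
  mis <- classify_mutation(rec_df("substitution", 4, 4, "A", "G"), m2)
  expect_equal(mis$effect, "missense")  # AAA -> GAA (Lys -> Glu)
  expect_equal(mis$first_affected_codon, 2L)
})

test_that("indel frame arithmetic forces frameshift vs in-frame classes", {
  m <- socs1_model()
  del1 <- classify_mutation(rec_df("deletion", 100, 100,
                                   substr(m$cds, 100, 100), ""), m)
  expect_equal(del1$effect, "frameshift")
  del3 <- classify_mutation(rec_df("deletion", 100, 102,
                                   substr(m$cds, 100, 102), ""), m)
  expect_equal(del3$effect, "inframe_deletion")
  dup2 <- classify_mutation(rec_df("duplication", 50, 51,
                                   substr(m$cds, 50, 51), substr(m$cds, 50, 51)), m)
  expect_equal(dup2$effect, "frameshift")
  ins3 <- classify_mutation(rec_df("insertion", 70, 70, "", "ACG"), m)
  expect_equal(ins3$effect, "inframe_insertion")
})

test_that("intact coding length obeys the per-event minimum rule", {
  m <- socs1_model()
  # empty case: full length, not truncating
  cc0 <- apply_case_mutations(rec_df("substitution", 1, 1, "x", "y")[0, ], m,
                              case_id = "empty")
  expect_equal(cc0$intact_cds_length, 636L)
  expect_false(cc0$truncating)

  # single stop gain at codon 10 -> 27 nt intact
  stop10 <- NULL
  for (off in 0:2) {
    p <- 3 * 9 + 1 + off
    ref <- substr(m$cds, p, p)
    for (a in setdiff(c("A", "C", "G", "T"), ref)) {
      r <- rec_df("substitution", p, p, ref, a)
      if (classify_mutation(r, m)$effect == "nonsense") { stop10 <- r; break }
    }
    if (!is.null(stop10)) break
  }
  expect_false(is.null(stop10))
  cc <- apply_case_mutations(stop10, m)
  expect_equal(cc$intact_cds_length, 27L)
  expect_true(cc$truncating)

  # 1-nt deletion at c.100 plus a missense at c.50 -> 99
  p50 <- substr(m$cds, 50, 50)
  mis <- NULL
  for (a in setdiff(c("A", "C", "G", "T"), p50)) {
    r <- rec_df("substitution", 50, 50, p50, a)
    if (classify_mutation(r, m)$effect %in% c("missense", "silent")) { mis <- r; break }
  }
  both <- rbind(rec_df("deletion", 100, 100, substr(m$cds, 100, 100), ""), mis)
  cc2 <- apply_case_mutations(both, m)
  expect_equal(cc2$intact_cds_length, 99L)
})

test_that("mutant sequence construction agrees with an independent translator", {
  # for truncating cases the mutant protein's first divergence from the
  # reference protein lies at codon floor(intact/3) + 1 or later
  m <- socs1_model()
  ref_prot <- oracle_translate(m$cds)
  set.seed(31)
  checked <- 0
  for (i in 1:60) {
    recs <- random_case(m, sample(1:3, 1))
    # keep only frameshift / stop-gain events: substitutions and in-frame
    # indels may legitimately change the protein upstream of the intact bound
    keep <- vapply(seq_len(nrow(recs)), function(j) {
      classify_mutation(recs[j, , drop = FALSE], m)$effect %in%
        c("nonsense", "frameshift")
    }, logical(1))
    recs <- recs[keep, , drop = FALSE]
    if (nrow(recs) == 0L) next
    cc <- tryCatch(suppressWarnings(apply_case_mutations(recs, m)),
                   error = function(e) NULL)
    if (is.null(cc) || !cc$truncating) next
    mut_prot <- oracle_translate(substr(cc$mutant_cds, 1,
                                        3 * (nchar(cc$mutant_cds) %/% 3)))
    k <- cc$intact_cds_length %/% 3
    if (k > 0) {
      expect_equal(substr(mut_prot, 1, k), substr(ref_prot, 1, k),
                   info = paste(recs$kind, recs$c_start, collapse = " | "))
    }
    checked <- checked + 1
  }
  expect_gt(checked, 10)
})

test_that("overlapping deletions error; same-position substitutions warn", {
  m <- socs1_model()
  d1 <- rec_df("deletion", 10, 14, substr(m$cds, 10, 14), "")
  d2 <- rec_df("deletion", 12, 13, substr(m$cds, 12, 13), "")
  expect_error(apply_case_mutations(rbind(d1, d2), m), "conflicting events")
  p <- substr(m$cds, 30, 30)
  alts <- setdiff(c("A", "C", "G", "T"), p)
  s1 <- rec_df("substitution", 30, 30, p, alts[1])
  s2 <- rec_df("substitution", 30, 30, p, alts[2])
  expect_warning(cc <- apply_case_mutations(rbind(s1, s2), m), "last wins")
  expect_equal(substr(cc$mutant_cds, 30, 30), alts[2])
})

test_that("domain impact separates direct, conservative and aggressive", {
  m <- socs1_model()
  socs_start <- m$domains$nt_start[m$domains$name == "SOCS box"]

  # stop gain strictly upstream of the SOCS box start: lost under both schemes
  stopg <- NULL
  for (p in 200:260) {
    ref <- substr(m$cds, p, p)
    for (a in setdiff(c("A", "C", "G", "T"), ref)) {
      r <- rec_df("substitution", p, p, ref, a)
      if (classify_mutation(r, m)$effect == "nonsense") { stopg <- r; break }
    }
    if (!is.null(stopg)) break
  }
  cc <- apply_case_mutations(stopg, m)
  expect_true("SOCS box" %in% cc$affected_conservative)
  expect_true("SOCS box" %in% cc$affected_aggressive)

  # in-frame 3-nt deletion upstream of the SOCS box: position shift counts
  # only under the aggressive weighting
  p <- 301L
  del3 <- rec_df("deletion", p, p + 2L, substr(m$cds, p, p + 2L), "")
  cc2 <- apply_case_mutations(del3, m)
  expect_true("SOCS box" %in% cc2$affected_aggressive)
  expect_false("SOCS box" %in% cc2$affected_conservative)

  # substitutions only: no downstream impact beyond direct hits
  p50 <- substr(m$cds, 50, 50)
  a50 <- setdiff(c("A", "C", "G", "T"), p50)
  subs <- rec_df("substitution", 50, 50, p50, a50[1])
  if (classify_mutation(subs, m)$effect == "nonsense") {
    subs <- rec_df("substitution", 50, 50, p50, a50[2])
  }
  cc3 <- apply_case_mutations(subs, m)
  expect_setequal(cc3$affected_conservative, cc3$affected_direct)
  expect_setequal(cc3$affected_aggressive, cc3$affected_direct)
})

test_that("impact-set and monotonicity invariants hold over random cases", {
  m <- socs1_model()
  set.seed(41)
  for (i in 1:200) {
    recs <- random_case(m, sample(1:4, 1))
    cc <- tryCatch(suppressWarnings(apply_case_mutations(recs, m)),
                   error = function(e) NULL)
    if (is.null(cc)) next
    # conservative subset of aggressive
    expect_true(all(cc$affected_conservative %in% cc$affected_aggressive))
    # duplicating an event changes nothing (idempotence)
    cc_dup <- suppressWarnings(
      apply_case_mutations(rbind(recs, recs[1, , drop = FALSE]), m))
    if (!is.null(cc_dup)) {
      expect_equal(cc_dup$intact_cds_length, cc$intact_cds_length)
      expect_setequal(cc_dup$affected_aggressive, cc$affected_aggressive)
    }
    # adding a length-altering event only shrinks intact length / grows sets
    extra <- random_record(m, kinds = c("deletion", "insertion"))
    cc_more <- tryCatch(suppressWarnings(
      apply_case_mutations(rbind(recs, extra), m)), error = function(e) NULL)
    if (!is.null(cc_more)) {
      expect_lte(cc_more$intact_cds_length, cc$intact_cds_length)
      expect_true(all(cc$affected_aggressive %in% cc_more$affected_aggressive))
    }
  }
})
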