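# Hypermutation hotspot machinery: motif scanning, targeting flags,
# deletion flanks, summaries and the permutation enrichment test.

test_that("hand-matched toy sequences produce the expected hits", {
  hits <- scan_motifs("AGCT")
  # AGCT matches RGYW (A=R? no: R is A/G -> A yes; G; C=Y; T=W) and DGYW
  rg <- hits[hits$family == "RGYW", ]
  dg <- hits[hits$family == "DGYW", ]
  expect_equal(rg$start, 1L); expect_equal(rg$mutable_position, 2L)
  expect_equal(dg$start, 1L); expect_equal(dg$mutable_position, 2L)

  hits_ta <- scan_motifs("TA")
  expect_equal(hits_ta$mutable_position[hits_ta$family == "TW"], 1L)
  expect_equal(hits_ta$mutable_position[hits_ta$family == "WA"], 2L)

  expect_equal(nrow(scan_motifs("CCCCCC")), 0L)
  expect_error(scan_motifs("ACGN"), "non-ACGT")
})

test_that("scanning agrees exactly with the naive sliding-window oracle", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(10:300, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    got <- scan_motifs(seq)
    want <- naive_scan_all(seq)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = substr(seq, 1, 30))
  }
})

test_that("both-strand closure: hits mirror under reverse complement", {
  partner <- c(RGYW = "WRCY", WRCY = "RGYW", DGYW = "WRCH", WRCH = "DGYW",
               WA = "TW", TW = "WA")
  set.seed(81)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    fwd <- scan_motifs(seq)
    rev <- scan_motifs(revcomp(seq))
    expect_equal(nrow(fwd), nrow(rev))
    # family-swapped, position-mirrored hit sets are identical
    mirrored <- data.frame(family = unname(partner[rev$family]),
                           start = n + 1L - rev$end,
                           end = n + 1L - rev$start,
                           mutable_position = n + 1L - rev$mutable_position)
    key <- function(d) sort(paste(d$family, d$start, d$mutable_position))
    expect_equal(key(fwd), key(mirrored))
  }
})

test_that("every RGYW hit position is also a DGYW hit (R within D)", {
  set.seed(91)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    h <- scan_motifs(seq)
    rg <- h$start[h$family == "RGYW"]
    dg <- h$start[h$family == "DGYW"]
    expect_true(all(rg %in% dg))
  }
})

test_that("is_shm_targeted flags motif positions and CDS-edge uncertainty", {
  # a model whose CDS carries AGCT at a known interior position
  cds <- "ATGAGCTCCCCGCCGCCCTGA"
  dom <- data.frame(name = "D", aa_start = 1L, aa_end = 2L, is_cterminal = TRUE)
  m <- gene_model("T", cds, dom, cds_offset_in_exon2 = 1L)
  # position 5 is the G of AGCT at 4..7 -> mutable
  r <- data.frame(case_id = "x", kind = "substitution", c_start = 5L, c_end = 5L,
                  ref = substr(cds, 5, 5), alt = "T", stringsAsFactors = FALSE)
  hit <- is_shm_targeted(r, m)
  expect_true(hit$targeted)
  expect_true("RGYW" %in% hit$families)

  # a position inside the C run is untargeted
  r2 <- data.frame(case_id = "x", kind = "substitution", c_start = 11L,
                   c_end = 11L, ref = substr(cds, 11, 11), alt = "A",
                   stringsAsFactors = FALSE)
  expect_false(is_shm_targeted(r2, m)$targeted)

  # c.1 with no upstream context carries the boundary-uncertain flag
  r3 <- data.frame(case_id = "x", kind = "substitution", c_start = 1L,
                   c_end = 1L, ref = "A", alt = "G", stringsAsFactors = FALSE)
  expect_true(is_shm_targeted(r3, m)$boundary_uncertain)
  # with context supplied the flag clears
  m2 <- gene_model("T", cds, dom, upstream_context = "GGGG",
                   downstream_context = "GGGG", cds_offset_in_exon2 = 1L)
  expect_false(is_shm_targeted(r3, m2)$boundary_uncertain)

  del <- data.frame(case_id = "x", kind = "deletion", c_start = 10L, c_end = 12L,
                    ref = substr(cds, 10, 12), alt = "", stringsAsFactors = FALSE)
  expect_error(is_shm_targeted(del, m), "not applicable")
})

test_that("deletion flanks test the window outside each breakpoint", {
  # CDS with AGCT immediately 5' of a deletable C run
  cds <- "ATGAGCTCCCCCCCCCCCTGA"
  dom <- data.frame(name = "D", aa_start = 1L, aa_end = 2L, is_cterminal = TRUE)
  m <- gene_model("T", cds, dom, cds_offset_in_exon2 = 1L)
  # delete c.8..10 (Cs); left window [4..7] holds AGCT
  del <- data.frame(case_id = "x", kind = "deletion", c_start = 8L, c_end = 10L,
                    ref = substr(cds, 8, 10), alt = "", stringsAsFactors = FALSE)
  fl <- deletion_flank_shm(del, m, window = 4)
  expect_true(fl$left)
  expect_identical(deletion_flank_shm(del, m, window = 0),
                   list(left = FALSE, right = FALSE))
  # deletion deep inside a C homopolymer with C-only flanks: both negative
  del2 <- data.frame(case_id = "x", kind = "deletion", c_start = 13L,
                     c_end = 14L, ref = substr(cds, 13, 14), alt = "",
                     stringsAsFactors = FALSE)
  fl2 <- deletion_flank_shm(del2, m, window = 2)
  expect_false(fl2$left)
  sub <- data.frame(case_id = "x", kind = "substitution", c_start = 5L,
                    c_end = 5L, ref = substr(cds, 5, 5), alt = "T",
                    stringsAsFactors = FALSE)
  expect_error(deletion_flank_shm(sub, m), "not applicable")
})

test_that("cohort summaries match exhaustive enumeration on a toy cohort", {
  m <- socs1_model()
  mut_pos <- mutable_positions(m)
  non_mut <- setdiff(seq_len(m$L), mut_pos)
  pick_sub <- function(p, id) {
    ref <- substr(m$cds, p, p)
    data.frame(case_id = id, kind = "substitution", c_start = p, c_end = p,
               ref = ref, alt = setdiff(c("A", "C", "G", "T"), ref)[1],
               stringsAsFactors = FALSE)
  }
  recs <- rbind(pick_sub(mut_pos[5], "a"), pick_sub(mut_pos[9], "a"),
                pick_sub(non_mut[3], "b"))
  s <- summarize_shm(recs, m)
  expect_equal(s$n_point, 3L)
  expect_equal(s$n_at_motif, 2L)
  expect_equal(s$fraction, 2 / 3)
  expect_equal(s$n_gc + s$n_at, 3L)
  expect_equal(s$n_gc_at_motif + s$n_at_at_motif, 2L)

  empty <- summarize_shm(recs[0, ], m)
  expect_equal(empty$n_point, 0L)
  expect_true(is.na(empty$fraction))

  all_on <- rbind(pick_sub(mut_pos[1], "c"), pick_sub(mut_pos[2], "c"))
  expect_equal(summarize_shm(all_on, m)$fraction, 1)
})

test_that("the enrichment test is powered at high bias and reproducible", {
  m <- socs1_model()
  p <- sim_params(n_cases = 120, shm_target_prob = 0.8, seed = 5)
  ch <- generate_cohort(p, m)
  et1 <- shm_enrichment_test(ch$mutations, m, B = 2000, seed = 13)
  et2 <- shm_enrichment_test(ch$mutations, m, B = 2000, seed = 13)
  expect_identical(et1$p, et2$p)
  expect_lt(et1$p, 0.01)
  expect_error(shm_enrichment_test(ch$mutations[0, ], m, B = 10, seed = 1),
               "no substitutions")
  # maximal observed count -> p near its floor
  mut_pos <- mutable_positions(m)
  recs <- do.call(rbind, lapply(mut_pos[1:10], function(pp) {
    ref <- substr(m$cds, pp, pp)
    data.frame(case_id = "z", kind = "substitution", c_start = pp, c_end = pp,
               ref = ref, alt = setdiff(c("A", "C", "G", "T"), ref)[1],
               stringsAsFactors = FALSE)
  }))
  et3 <- shm_enrichment_test(recs, m, B = 500, seed = 3)
  expect_lte(et3$p, 0.05)
})
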