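# Independent oracles and small fixture builders used across test files.

# Naive O(n*k) sliding-window IUPAC matcher, independent of the scanning
# route used by the package.
.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"))

naive_scan <- function(seq, pattern, family, mutable_offset) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  k <- length(p); n <- length(s)
  hits <- integer(0)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!s[i + j - 1] %in% .iupac[[p[j]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(family = character(0), start = integer(0),
                      end = integer(0), mutable_position = integer(0)))
  }
  data.frame(family = family, start = hits, end = hits + k - 1L,
             mutable_position = hits + mutable_offset)
}

naive_scan_all <- function(seq) {
  specs <- shm_motifs()
  out <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    naive_scan(seq, specs$pattern[i], specs$family[i], specs$mutable_offset[i])
  }))
  out[order(out$start, out$family), , drop = FALSE]
}

# Independent translation oracle (seqinr's codon machinery, not the
# package's lookup path).
oracle_translate <- function(cds) {
  paste(seqinr::translate(seqinr::s2c(tolower(cds))), collapse = "")
}

# Breslow partial log-likelihood written from the definition, independent of
# the package's breslow_loglik and of survival::coxph.
oracle_breslow_loglik <- function(beta, x, times, events) {
  eta <- x * beta
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

# Two-stage 1-D grid maximizer of the oracle partial likelihood.
oracle_grid_cox <- function(x, times, events, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, oracle_breslow_loglik, numeric(1), x = x,
               times = times, events = events)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_breslow_loglik, numeric(1), x = x,
                times = times, events = events)
  fine[which.max(llf)]
}

# A tiny fully-specified gene model used where the packaged one is too big:
# 30-nt CDS (9 aa + stop), two domains, the second C-terminal.
tiny_model <- function(cds = NULL, up = "", down = "") {
  if (is.null(cds)) cds <- "ATGGCTAAATACCCAGGGTGGCGACAATGA"
  gene_model("TINY", cds,
             data.frame(name = c("D1", "D2"),
                        aa_start = c(2L, 7L), aa_end = c(4L, 9L),
                        is_cterminal = c(FALSE, TRUE)),
             upstream_context = up, downstream_context = down,
             cds_offset_in_exon2 = 101L, strict = TRUE)
}

# Random valid mutation record against a model (for round-trip and
# invariance property tests).
random_record <- function(model, case_id = "X", kinds = .mutation_kinds_test) {
  kind <- sample(kinds, 1)
  L <- model$L
  if (kind == "substitution") {
    p <- sample(L, 1)
    ref <- substr(model$cds, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    data.frame(case_id = case_id, kind = kind, c_start = p, c_end = p,
               ref = ref, alt = alt, stringsAsFactors = FALSE)
  } else if (kind %in% c("deletion", "duplication")) {
    w <- sample(1:4, 1)
    p <- sample(L - w + 1, 1)
    slice <- substr(model$cds, p, p + w - 1)
    data.frame(case_id = case_id, kind = kind, c_start = p, c_end = p + w - 1,
               ref = slice, alt = if (kind == "duplication") slice else "",
               stringsAsFactors = FALSE)
  } else {
    p <- sample(L - 1, 1)
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), replace = TRUE),
                 collapse = "")
    data.frame(case_id = case_id, kind = kind, c_start = p, c_end = p,
               ref = "", alt = ins, stringsAsFactors = FALSE)
  }
}

.mutation_kinds_test <- c("substitution", "deletion", "duplication", "insertion")

# Random non-overlapping-deletion case (a list of records for one case).
random_case <- function(model, n_mut, case_id = "X") {
  recs <- NULL
  for (i in seq_len(n_mut)) {
    for (attempt in 1:50) {
      r <- random_record(model, case_id)
      if (r$kind == "deletion" && !is.null(recs)) {
        dels <- recs[recs$kind == "deletion", , drop = FALSE]
        if (nrow(dels) > 0 &&
            any(r$c_start <= dels$c_end & r$c_end >= dels$c_start)) next
      }
      recs <- rbind(recs, r)
      break
    }
  }
  recs
}
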