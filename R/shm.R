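# Somatic-hypermutation hotspot machinery: degenerate motif scanning on both
# strands, per-mutation targeting flags, deletion-flank checks, cohort
# summaries and a permutation enrichment test.

#' Somatic-hypermutation hotspot motif specifications
#'
#' The six motif families with their IUPAC patterns and the 0-based offset of
#' the mutable base inside the pattern: RGYW/WRCY and DGYW/WRCH (mutable G:C)
#' and WA/TW (mutable A:T). Each family's reverse-complement partner is in the
#' set, so scanning the forward strand for all six realizes both-strand
#' scanning (R = A/G, Y = C/T, W = A/T, D = A/G/T, H = A/C/T).
#'
#' @return Data frame with `family`, `pattern`, `mutable_offset`.
#' @export
shm_motifs <- function() {
  data.frame(
    family = c("RGYW", "WRCY", "DGYW", "WRCH", "WA", "TW"),
    pattern = c("RGYW", "WRCY", "DGYW", "WRCH", "WA", "TW"),
    mutable_offset = c(1L, 2L, 1L, 2L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for hypermutation hotspot motifs
#'
#' Reports every occurrence of every family at every offset, including
#' overlapping and nested hits; an RGYW hit is also reported as a DGYW hit
#' (no deduplication across families).
#'
#' @param seq DNA string over A/C/G/T.
#' @return Data frame with `family`, `start` (1-based), `end`, and
#'   `mutable_position` (= start + mutable offset), ordered by start then
#'   family.
#' @export
scan_motifs <- function(seq) {
  seq <- toupper(seq)
  .check_dna(seq, "sequence")
  specs <- shm_motifs()
  subject <- Biostrings::DNAString(seq)
  out <- lapply(seq_len(nrow(specs)), function(i) {
    if (nchar(seq) < nchar(specs$pattern[i])) return(NULL)
    m <- Biostrings::matchPattern(specs$pattern[i], subject, fixed = FALSE)
    if (length(m) == 0L) return(NULL)
    st <- BiocGenerics::start(m)
    data.frame(family = specs$family[i], start = st,
               end = BiocGenerics::end(m),
               mutable_position = st + specs$mutable_offset[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(family = character(0), start = integer(0),
                      end = integer(0), mutable_position = integer(0))
  }
  out[order(out$start, out$family), , drop = FALSE]
}

# Scan the context-extended reference and translate hit coordinates to the
# CDS frame (positions may be < 1 or > L when a hit lies in the context).
.scan_model_motifs <- function(model) {
  ext <- paste0(model$upstream_context, model$cds, model$downstream_context)
  off <- nchar(model$upstream_context)
  hits <- scan_motifs(ext)
  hits$start <- hits$start - off
  hits$end <- hits$end - off
  hits$mutable_position <- hits$mutable_position - off
  hits
}

#' CDS positions mutable under the hotspot model
#'
#' @param model A [gene_model()].
#' @return Sorted unique CDS positions (within `[1, L]`) that are the mutable
#'   base of at least one motif hit on the context-extended reference.
#' @export
mutable_positions <- function(model) {
  hits <- .scan_model_motifs(model)
  p <- hits$mutable_position
  sort(unique(p[p >= 1L & p <= model$L]))
}

#' Is a substitution at a hypermutation-mutable position?
#'
#' True iff the substituted position coincides with the mutable base of at
#' least one motif hit on the context-extended reference. Positions within
#' 3 nt of a CDS edge that has no flanking context carry a boundary-uncertain
#' flag (a motif overlapping the edge could not be seen).
#'
#' @param record One-row substitution record.
#' @param model A [gene_model()].
#' @return List with `targeted` (logical), `families` (character),
#'   `boundary_uncertain` (logical).
#' @export
is_shm_targeted <- function(record, model) {
  stopifnot(nrow(record) == 1L)
  if (record$kind != "substitution") {
    stop("not applicable: is_shm_targeted takes substitutions; use deletion_flank_shm for deletions",
         call. = FALSE)
  }
  hits <- .scan_model_motifs(model)
  at <- hits[hits$mutable_position == record$c_start, , drop = FALSE]
  p <- record$c_start
  uncertain <- (p <= 3L && !nzchar(model$upstream_context)) ||
    (p >= model$L - 2L && !nzchar(model$downstream_context))
  list(targeted = nrow(at) > 0L,
       families = unique(at$family),
       boundary_uncertain = uncertain)
}

#' Are a deletion's flanks at hypermutation sites?
#'
#' A flank is positive iff some motif hit's span intersects the `window`
#' nucleotides immediately outside that breakpoint (left: positions
#' `[c_start - window, c_start - 1]`; right: `[c_end + 1, c_end + window]`,
#' both in CDS coordinates, context included in the scan).
#'
#' @param record One-row deletion record.
#' @param model A [gene_model()].
#' @param window Flank width in nt; default 4 (one motif length).
#' @return List with logical `left` and `right`.
#' @export
deletion_flank_shm <- function(record, model, window = 4L) {
  stopifnot(nrow(record) == 1L)
  if (record$kind != "deletion") {
    stop("not applicable: deletion_flank_shm takes deletions", call. = FALSE)
  }
  window <- as.integer(window)
  if (window <= 0L) return(list(left = FALSE, right = FALSE))
  hits <- .scan_model_motifs(model)
  spans <- function(lo, hi) any(hits$start <= hi & hits$end >= lo)
  list(left = spans(record$c_start - window, record$c_start - 1L),
       right = spans(record$c_end + 1L, record$c_end + window))
}

#' Summarize hypermutation-motif targeting over a cohort
#'
#' Counts point mutations (substitutions), how many sit at mutable motif
#' positions, the targeted fraction, the split by reference base class
#' (G/C vs A/T), and per-family hit counts.
#'
#' @param mutations Mutation record data frame.
#' @param model A [gene_model()].
#' @return List with `n_point`, `n_at_motif`, `fraction` (NA for an empty
#'   cohort), `n_gc`, `n_gc_at_motif`, `n_at`, `n_at_at_motif`, and
#'   `per_family` (named integer vector of substitution counts whose position
#'   is mutable under each family).
#' @export
summarize_shm <- function(mutations, model) {
  subs <- mutations[mutations$kind == "substitution", , drop = FALSE]
  specs <- shm_motifs()
  hits <- .scan_model_motifs(model)
  per_family <- stats::setNames(integer(nrow(specs)), specs$family)
  n_at_motif <- 0L
  gc <- subs$ref %in% c("G", "C")
  n_gc_at <- 0L; n_at_at <- 0L
  for (i in seq_len(nrow(subs))) {
    at <- hits[hits$mutable_position == subs$c_start[i], , drop = FALSE]
    if (nrow(at) > 0L) {
      n_at_motif <- n_at_motif + 1L
      if (gc[i]) n_gc_at <- n_gc_at + 1L else n_at_at <- n_at_at + 1L
      for (fam in unique(at$family)) per_family[fam] <- per_family[fam] + 1L
    }
  }
  list(
    n_point = nrow(subs),
    n_at_motif = n_at_motif,
    fraction = if (nrow(subs) == 0L) NA_real_ else n_at_motif / nrow(subs),
    n_gc = sum(gc),
    n_gc_at_motif = n_gc_at,
    n_at = sum(!gc),
    n_at_at_motif = n_at_at,
    per_family = per_family
  )
}

#' Permutation test for hypermutation-motif enrichment
#'
#' Compares the observed number of substitutions at mutable motif positions
#' with its null distribution under uniform random repositioning of the same
#' number of substitutions over the CDS. One-sided with add-one correction:
#' `p = (r + 1) / (B + 1)` where `r` counts permutations whose at-motif count
#' is at least the observed one.
#'
#' @param mutations Mutation record data frame (must contain at least one
#'   substitution).
#' @param model A [gene_model()].
#' @param B Number of permutations (>= 1).
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @return List with `p`, `observed`, `n_substitutions`, `B`,
#'   `background_density` (fraction of CDS positions that are mutable).
#' @export
shm_enrichment_test <- function(mutations, model, B = 1000L, seed = 1L) {
  stopifnot(B >= 1L)
  subs <- mutations[mutations$kind == "substitution", , drop = FALSE]
  n <- nrow(subs)
  if (n == 0L) stop("no substitutions to test", call. = FALSE)
  mut_pos <- mutable_positions(model)
  observed <- sum(subs$c_start %in% mut_pos)
  is_mut <- logical(model$L)
  is_mut[mut_pos] <- TRUE
  r <- .with_seed(seed, {
    counts <- vapply(seq_len(B), function(b) {
      sum(is_mut[sample.int(model$L, n, replace = TRUE)])
    }, integer(1))
    sum(counts >= observed)
  })
  list(p = (r + 1) / (B + 1), observed = observed, n_substitutions = n,
       B = as.integer(B), background_density = length(mut_pos) / model$L)
}
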