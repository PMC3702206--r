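# Protein-level consequences: per-mutation effect classes, per-case mutant
# sequence, intact coding length, and direct vs downstream domain impact
# under the conservative and aggressive weighting schemes.

# Net change in sequence length caused by one event (nt).
.net_length_change <- function(record) {
  switch(record$kind,
    substitution = 0L,
    deletion = -(record$c_end - record$c_start + 1L),
    duplication = record$c_end - record$c_start + 1L,
    insertion = nchar(record$alt),
    stop("unknown kind", call. = FALSE))
}

# Does a substitution create a premature stop in the reference frame?
# Returns the stop codon index, or NA.
.stop_gain_codon <- function(record, model) {
  if (record$kind != "substitution") return(NA_integer_)
  cod <- (record$c_start - 1L) %/% 3L + 1L
  s <- 3L * (cod - 1L) + 1L
  codon <- substr(model$cds, s, s + 2L)
  substr(codon, record$c_start - s + 1L, record$c_start - s + 1L) <- record$alt
  ref_codon <- substr(model$cds, s, s + 2L)
  if (codon %in% .stop_codons && !ref_codon %in% .stop_codons) cod else NA_integer_
}

#' Classify a single mutation's protein-level effect
#'
#' Substitutions are translated in the reference frame at the affected codon:
#' same amino acid is silent, a different one missense, a new stop nonsense.
#' Indels with net length change not divisible by 3 are frameshifts;
#' in-frame indels are `inframe_deletion` / `inframe_duplication` /
#' `inframe_insertion`.
#'
#' @param record One-row validated mutation record.
#' @param model A [gene_model()].
#' @return Data frame with `effect`, `first_affected_codon`,
#'   `premature_stop_at` (NA unless nonsense).
#' @export
classify_mutation <- function(record, model) {
  stopifnot(nrow(record) == 1L)
  cod <- (record$c_start - 1L) %/% 3L + 1L
  if (record$kind == "substitution") {
    stop_at <- .stop_gain_codon(record, model)
    if (!is.na(stop_at)) {
      eff <- "nonsense"
    } else {
      s <- 3L * (cod - 1L) + 1L
      ref_codon <- substr(model$cds, s, s + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, record$c_start - s + 1L, record$c_start - s + 1L) <- record$alt
      tab <- .codon_table()
      eff <- if (tab[ref_codon] == tab[alt_codon]) "silent" else "missense"
    }
    return(data.frame(effect = eff, first_affected_codon = cod,
                      premature_stop_at = if (eff == "nonsense") stop_at else NA_integer_))
  }
  net <- .net_length_change(record)
  eff <- if (net %% 3L != 0L) {
    "frameshift"
  } else {
    switch(record$kind,
           deletion = "inframe_deletion",
           duplication = "inframe_duplication",
           insertion = "inframe_insertion")
  }
  data.frame(effect = eff, first_affected_codon = cod,
             premature_stop_at = NA_integer_)
}

#' Annotate every mutation in a table
#'
#' @param records Mutation record data frame.
#' @param model A [gene_model()].
#' @return The records with added columns `c_notation`, `effect`,
#'   `first_affected_codon`, `premature_stop_at`.
#' @export
annotate_mutations <- function(records, model) {
  if (nrow(records) == 0L) {
    return(cbind(records, data.frame(c_notation = character(0),
                                     effect = character(0),
                                     first_affected_codon = integer(0),
                                     premature_stop_at = integer(0))))
  }
  ann <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    classify_mutation(records[i, , drop = FALSE], model)
  }))
  cn <- vapply(seq_len(nrow(records)),
               function(i) format_c_notation(records[i, , drop = FALSE]),
               character(1))
  cbind(records, data.frame(c_notation = cn, stringsAsFactors = FALSE), ann)
}

# Build the mutant CDS by applying events in descending c_start order, so
# stored reference coordinates never need re-mapping. Overlapping
# substitutions at one position: file order, last one wins (warning).
.build_mutant_cds <- function(records, model) {
  chars <- strsplit(model$cds, "", fixed = TRUE)[[1L]]
  if (nrow(records) == 0L) return(paste(chars, collapse = ""))
  dels <- records[records$kind == "deletion", , drop = FALSE]
  if (nrow(dels) > 1L) {
    o <- order(dels$c_start)
    if (any(dels$c_start[o][-1L] <= dels$c_end[o][-nrow(dels)])) {
      stop("conflicting events: overlapping deletion intervals within one case",
           call. = FALSE)
    }
  }
  subs <- records[records$kind == "substitution", , drop = FALSE]
  if (anyDuplicated(subs$c_start) > 0L) {
    warning("multiple substitutions at one position; applying in file order (last wins)",
            call. = FALSE)
  }
  # stable sort: descending position, file order preserved within a position
  ord <- order(-records$c_start, seq_len(nrow(records)))
  pieces <- as.list(chars)
  for (i in ord) {
    r <- records[i, , drop = FALSE]
    p <- r$c_start; q <- r$c_end
    switch(r$kind,
      substitution = { pieces[[p]] <- r$alt },
      deletion = { for (j in p:q) pieces[[j]] <- "" },
      duplication = { pieces[[q]] <- paste0(pieces[[q]], substr(model$cds, p, q)) },
      insertion = { pieces[[p]] <- paste0(pieces[[p]], r$alt) })
  }
  paste(unlist(pieces), collapse = "")
}

# Intact-length bound contributed by one event (nt of 5' reference preserved
# in frame): frame-disrupting events bound at c_start - 1; stop-gain
# substitutions at 3*(stop codon - 1). In-frame indels keep the downstream
# frame, so they never shorten the intact length (their impact is captured
# by the domain-weighting schemes instead), and neither do other
# substitutions.
.event_bound <- function(record, model) {
  if (record$kind == "substitution") {
    s <- .stop_gain_codon(record, model)
    if (is.na(s)) model$L else as.integer(3L * (s - 1L))
  } else if (.net_length_change(record) %% 3L != 0L) {
    as.integer(record$c_start - 1L)
  } else {
    model$L
  }
}

.event_is_length_altering <- function(record) {
  record$kind %in% c("deletion", "duplication", "insertion")
}

#' Merge a case's mutations into a case-level consequence
#'
#' Builds the mutant CDS, the intact coding length (minimum over the per-event
#' bounds: `c_start - 1` for every frame-disrupting event, `3*(s-1)` for a
#' stop gain at codon `s`, and the full CDS length when no such event exists),
#' the truncating flag, and the direct / conservative / aggressive
#' affected-domain sets.
#'
#' @param records Mutation records of a single case (possibly zero rows).
#' @param model A [gene_model()].
#' @param case_id Case identifier; defaults to the records' shared `case_id`.
#' @return Object of class `case_consequence`: list with `case_id`,
#'   `n_mutations` (distinct events; exact duplicate rows collapse), `mutant_cds`, `intact_cds_length`, `truncating`,
#'   `affected_direct`, `affected_conservative`, `affected_aggressive`.
#' @export
apply_case_mutations <- function(records, model, case_id = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(records) > 0L) {
    ids <- unique(records$case_id[!is.na(records$case_id)])
    if (length(ids) > 1L) stop("records belong to more than one case: ",
                               paste(ids, collapse = ", "), call. = FALSE)
    if (is.null(case_id)) case_id <- if (length(ids) == 1L) ids else NA_character_
  }
  if (is.null(case_id)) case_id <- NA_character_
  # exact duplicate rows (retained and flagged at the I/O layer) are one
  # biological event here: severity is idempotent to duplication
  records <- unique(records)

  mutant <- .build_mutant_cds(records, model)
  bounds <- model$L
  if (nrow(records) > 0L) {
    bounds <- c(vapply(seq_len(nrow(records)),
                       function(i) .event_bound(records[i, , drop = FALSE], model),
                       integer(1)), model$L)
  }
  intact <- min(bounds)
  truncating <- intact < model$L

  cc <- structure(list(
    case_id = case_id,
    n_mutations = nrow(records),
    records = records,
    mutant_cds = mutant,
    intact_cds_length = intact,
    truncating = truncating
  ), class = "case_consequence")
  cc$affected_direct <- .impact_direct(records, model)
  cc$affected_conservative <- domain_impact(cc, model, "conservative")
  cc$affected_aggressive <- domain_impact(cc, model, "aggressive")
  cc
}

#' @export
print.case_consequence <- function(x, ...) {
  cat(sprintf("<case_consequence> %s: %d mutation(s), intact %d nt%s\n",
              x$case_id, x$n_mutations, x$intact_cds_length,
              if (x$truncating) " (truncating)" else ""))
  invisible(x)
}

.impact_direct <- function(records, model) {
  dom <- model$domains
  hit <- rep(FALSE, nrow(dom))
  for (i in seq_len(nrow(records))) {
    r <- records[i, , drop = FALSE]
    if (r$kind == "insertion") {
      # anchor gap between c_start and c_start+1 strictly inside the interval
      hit <- hit | (dom$nt_start <= r$c_start & r$c_start < dom$nt_end)
    } else {
      hit <- hit | (r$c_start <= dom$nt_end & r$c_end >= dom$nt_start)
    }
  }
  dom$name[hit]
}

#' Domains affected under a downstream-weighting scheme
#'
#' A domain is affected if it is hit directly (an event footprint intersects
#' its nucleotide interval) or through a downstream consequence of a 5'
#' length-altering/truncating event. Under the *conservative* weighting only
#' the complete loss of a domain counts: its whole interval must lie beyond
#' the intact coding length, or a deletion must remove it entirely. The
#' *aggressive* weighting also counts partial loss (any part of the interval
#' beyond the intact length), shifts of domain position (any net
#' length-changing event 5' of the domain start) and partial deletion.
#'
#' @param cc A `case_consequence` from [apply_case_mutations()].
#' @param model A [gene_model()].
#' @param scheme `"conservative"` or `"aggressive"`.
#' @return Character vector of affected domain names.
#' @export
domain_impact <- function(cc, model, scheme = c("conservative", "aggressive")) {
  scheme <- match.arg(scheme)
  dom <- model$domains
  records <- cc$records
  intact <- cc$intact_cds_length
  hit <- dom$name %in% .impact_direct(records, model)
  for (d in seq_len(nrow(dom))) {
    s <- dom$nt_start[d]; e <- dom$nt_end[d]
    if (scheme == "conservative") {
      if (s > intact) hit[d] <- TRUE
    } else {
      if (e > intact) hit[d] <- TRUE
    }
    for (i in seq_len(nrow(records))) {
      r <- records[i, , drop = FALSE]
      if (r$kind == "deletion") {
        if (scheme == "conservative") {
          if (r$c_start <= s && r$c_end >= e) hit[d] <- TRUE
        } else {
          if (r$c_start <= e && r$c_end >= s) hit[d] <- TRUE
        }
      }
      if (scheme == "aggressive" && .event_is_length_altering(r) &&
          .net_length_change(r) != 0L && r$c_start < s) {
        hit[d] <- TRUE
      }
    }
  }
  dom$name[hit]
}

#' Case consequences for a whole cohort
#'
#' @param mutations Mutation record data frame for many cases.
#' @param model A [gene_model()].
#' @param case_ids Optional full case roster; cases without mutation rows get
#'   an empty (wild-type) consequence.
#' @return Named list of `case_consequence` objects, one per case, in roster
#'   order (or first-appearance order of the mutation table).
#' @export
cohort_consequences <- function(mutations, model, case_ids = NULL) {
  if (is.null(case_ids)) case_ids <- unique(mutations$case_id)
  out <- lapply(case_ids, function(id) {
    apply_case_mutations(mutations[!is.na(mutations$case_id) &
                                     mutations$case_id == id, , drop = FALSE],
                         model, case_id = id)
  })
  names(out) <- case_ids
  out
}

#' Write the annotated consequence table
#'
#' One row per mutation (case, c. notation, effect, first affected codon)
#' followed by one row per case (intact length, truncating flag, and the
#' three affected-domain sets, semicolon-joined).
#'
#' @param mutations Mutation record data frame.
#' @param model A [gene_model()].
#' @param path Output TSV path.
#' @param case_ids Optional roster passed to [cohort_consequences()].
#' @return Invisibly, a list with the two data frames written
#'   (`mutations`, `cases`).
#' @export
write_consequence_table <- function(mutations, model, path, case_ids = NULL) {
  ann <- annotate_mutations(mutations, model)
  ccs <- cohort_consequences(mutations, model, case_ids)
  cases <- data.frame(
    case_id = names(ccs),
    n_mutations = vapply(ccs, function(x) x$n_mutations, integer(1)),
    intact_cds_length = vapply(ccs, function(x) x$intact_cds_length, integer(1)),
    truncating = vapply(ccs, function(x) x$truncating, logical(1)),
    affected_direct = vapply(ccs, function(x) paste(x$affected_direct, collapse = ";"), character(1)),
    affected_conservative = vapply(ccs, function(x) paste(x$affected_conservative, collapse = ";"), character(1)),
    affected_aggressive = vapply(ccs, function(x) paste(x$affected_aggressive, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  mut_out <- ann[, c("case_id", "c_notation", "effect", "first_affected_codon")]
  utils::write.table(mut_out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  case_path <- sub("(\\.tsv)?$", "_cases.tsv", path)
  utils::write.table(cases, case_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(mutations = mut_out, cases = cases))
}
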