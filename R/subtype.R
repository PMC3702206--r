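# Case-level severity subtyping (wild-type / minor / major) and the
# severity ordering used for per-case mutation plots.

# Is this single event foreshortening (capable of truncating the encoded
# protein)? Stop-gain substitutions, deletions (any frame) and
# frame-disrupting duplications/insertions qualify.
.is_foreshortening <- function(record, model) {
  if (record$kind == "substitution") return(!is.na(.stop_gain_codon(record, model)))
  if (record$kind == "deletion") return(TRUE)
  .net_length_change(record) %% 3L != 0L
}

#' Call the case-level mutation-severity subtype
#'
#' * `wild_type`: no mutations.
#' * `major`: at least one foreshortening event (stop gain, frameshift,
#'   deletion) whose aggressive-scheme impact — evaluated for that event
#'   alone — reaches a C-terminal domain ("presence or position" of the
#'   C-terminal domains is affected).
#' * `minor`: every event is a non-foreshortening point mutation.
#' * Remaining edge cases (foreshortening events that never reach a
#'   C-terminal domain; in-frame duplications/insertions only) are called
#'   `major` with `ambiguous = TRUE`: they are deleterious but local, and
#'   they are not point mutations, so the severity-conservative default is
#'   the severe class.
#'
#' @param records Mutation records of one case.
#' @param model A [gene_model()].
#' @param case_id Optional explicit case id.
#' @return One-row data frame: `case_id`, `call`, `ambiguous`, `basis`
#'   (semicolon-joined c. notation of the triggering events, empty for
#'   wild-type/minor).
#' @export
classify_case <- function(records, model, case_id = NULL) {
  if (nrow(records) > 0L && is.null(case_id)) {
    ids <- unique(records$case_id[!is.na(records$case_id)])
    case_id <- if (length(ids) == 1L) ids else NA_character_
  }
  if (is.null(case_id)) case_id <- NA_character_
  if (nrow(records) == 0L) {
    return(data.frame(case_id = case_id, call = "wild_type",
                      ambiguous = FALSE, basis = "", stringsAsFactors = FALSE))
  }
  fore <- vapply(seq_len(nrow(records)),
                 function(i) .is_foreshortening(records[i, , drop = FALSE], model),
                 logical(1))
  trigger <- logical(nrow(records))
  for (i in which(fore)) {
    one <- apply_case_mutations(records[i, , drop = FALSE], model,
                                case_id = case_id)
    if (length(intersect(one$affected_aggressive, model$cterm_names)) > 0L) {
      trigger[i] <- TRUE
    }
  }
  if (any(trigger)) {
    basis <- vapply(which(trigger),
                    function(i) format_c_notation(records[i, , drop = FALSE]),
                    character(1))
    return(data.frame(case_id = case_id, call = "major", ambiguous = FALSE,
                      basis = paste(unique(basis), collapse = ";"),
                      stringsAsFactors = FALSE))
  }
  non_fore_subst <- records$kind == "substitution" & !fore
  if (all(non_fore_subst)) {
    return(data.frame(case_id = case_id, call = "minor", ambiguous = FALSE,
                      basis = "", stringsAsFactors = FALSE))
  }
  # deleterious-but-local edge cases: severity-conservative default
  edge <- which(!non_fore_subst)
  basis <- vapply(edge, function(i) format_c_notation(records[i, , drop = FALSE]),
                  character(1))
  data.frame(case_id = case_id, call = "major", ambiguous = TRUE,
             basis = paste(unique(basis), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Subtype every case of a cohort
#'
#' @param mutations Mutation record data frame for the cohort.
#' @param model A [gene_model()].
#' @param case_ids Optional full roster; roster cases without mutation rows
#'   are wild-type.
#' @return Data frame, one row per case: `case_id`, `call`, `ambiguous`,
#'   `basis`.
#' @export
classify_cohort <- function(mutations, model, case_ids = NULL) {
  if (is.null(case_ids)) case_ids <- unique(mutations$case_id)
  do.call(rbind, lapply(case_ids, function(id) {
    classify_case(mutations[!is.na(mutations$case_id) &
                              mutations$case_id == id, , drop = FALSE],
                  model, case_id = id)
  }))
}

#' Order cases by predicted mutation severity
#'
#' Stable total order: ascending intact coding length (most foreshortened
#' first), then descending mutation count, then case id.
#'
#' @param consequences List of `case_consequence` objects
#'   (see [cohort_consequences()]).
#' @return Data frame ordered by severity with columns `case_id`,
#'   `intact_cds_length`, `n_mutations`.
#' @export
severity_sort <- function(consequences) {
  if (length(consequences) == 0L) {
    return(data.frame(case_id = character(0), intact_cds_length = integer(0),
                      n_mutations = integer(0)))
  }
  df <- data.frame(
    case_id = vapply(consequences, function(x) x$case_id, character(1)),
    intact_cds_length = vapply(consequences, function(x) x$intact_cds_length, integer(1)),
    n_mutations = vapply(consequences, function(x) x$n_mutations, integer(1)),
    stringsAsFactors = FALSE
  )
  df[order(df$intact_cds_length, -df$n_mutations, df$case_id), , drop = FALSE]
}
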