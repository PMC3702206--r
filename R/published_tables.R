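# Accessors for the packaged machine transcriptions of the published cohort
# tables, and the descriptive tallies / contingency tables built from them.

#' Packaged mutant-case characteristics table
#'
#' Machine transcription of the published per-case clinicopathological table
#' of the 24 mutant cases (immunophenotype, FISH, and the four expression
#' signature labels). `.` means not available.
#'
#' @return Data frame, one row per mutant case.
#' @export
socs1_mutant_cases <- function() {
  path <- system.file("extdata", "socs1_mutant_cases.tsv",
                      package = "socs1mut", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    na.strings = c(".", ""), check.names = FALSE)
}

#' Packaged cohort-level counts
#'
#' Total screened cases, mutant/subtype group sizes, and the wild-type
#' signature-label counts used to rebuild the status-by-signature
#' contingency tables.
#'
#' @return List as stored in the JSON fixture.
#' @export
socs1_cohort_counts <- function() {
  path <- system.file("extdata", "socs1_cohort_counts.json",
                      package = "socs1mut", mustWork = TRUE)
  jsonlite::fromJSON(path)
}

#' Positivity tally for a marker column
#'
#' Fraction of evaluable cases (pairwise exclusion of `NA`) positive for a
#' `+`/`-` marker column.
#'
#' @param cases Data frame (e.g. [socs1_mutant_cases()]).
#' @param column Marker column name.
#' @param positive Level counted as positive (default `"+"`).
#' @return List with `n_positive`, `n_evaluable`, `percent`.
#' @export
marker_tally <- function(cases, column, positive = "+") {
  if (!column %in% names(cases)) stop("unknown column: ", column, call. = FALSE)
  x <- cases[[column]]
  x <- x[!is.na(x)]
  list(n_positive = sum(x == positive),
       n_evaluable = length(x),
       percent = 100 * sum(x == positive) / length(x))
}

#' Mutation-status by signature-label contingency table
#'
#' Rebuilds the wild-type vs mutant table for one of the four expression
#' signatures: wild-type counts from the packaged cohort counts, mutant
#' counts tallied from the per-case table (cases with a missing label are
#' excluded).
#'
#' @param signature One of `"coo"`, `"mbl"`, `"pap"`, `"cc"`.
#' @param collapse Optional label to dichotomize on: the table becomes 2x2,
#'   label vs rest (e.g. `"PAP-1"`).
#' @return Integer matrix, rows `wild_type`/`mutant`, columns the labels.
#' @export
signature_status_table <- function(signature = c("coo", "mbl", "pap", "cc"),
                                   collapse = NULL) {
  signature <- match.arg(signature)
  counts <- socs1_cohort_counts()
  wt <- unlist(counts$wild_type_signature_counts[[signature]])
  cases <- socs1_mutant_cases()
  lab <- cases[[signature]]
  lab <- lab[!is.na(lab)]
  mut <- vapply(names(wt), function(l) sum(lab == l), integer(1))
  tab <- rbind(wild_type = wt, mutant = mut)
  if (!is.null(collapse)) {
    if (!collapse %in% colnames(tab)) stop("unknown label: ", collapse,
                                           call. = FALSE)
    tab <- cbind(tab[, collapse, drop = FALSE],
                 other = rowSums(tab[, colnames(tab) != collapse, drop = FALSE]))
  }
  storage.mode(tab) <- "integer"
  tab
}
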