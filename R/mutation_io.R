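# Mutation and clinical table I/O: the HGVS-style c. dialect, per-case
# mutation catalogs, clinical vocabularies, IPI and 0/1 covariate encodings.

.mutation_kinds <- c("substitution", "deletion", "duplication", "insertion")

# One-row mutation record data frame. ref/alt conventions:
#   substitution: single ref base, single alt base
#   deletion:     ref = deleted slice, alt = ""
#   duplication:  ref = duplicated slice, alt = duplicated slice
#   insertion:    ref = "", alt = inserted bases; anchored between
#                 c_start and c_start + 1, c_end = c_start
.mutation_record <- function(case_id, kind, c_start, c_end, ref, alt) {
  data.frame(case_id = case_id, kind = kind,
             c_start = as.integer(c_start), c_end = as.integer(c_end),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Validate mutation records against a gene model
#'
#' Checks coordinates against the CDS length and stated ref alleles against
#' the reference sequence; fills deletion/duplication `ref` from the reference
#' when empty.
#'
#' @param records Mutation data frame (`case_id`, `kind`, `c_start`, `c_end`,
#'   `ref`, `alt`).
#' @param model A [gene_model()].
#' @return The validated (ref-filled) records.
#' @export
validate_mutations <- function(records, model) {
  stopifnot(inherits(model, "gene_model"))
  if (nrow(records) == 0L) return(records)
  if (any(!records$kind %in% .mutation_kinds)) {
    stop("unknown mutation kind: ",
         records$kind[!records$kind %in% .mutation_kinds][1L], call. = FALSE)
  }
  bad <- records$c_start < 1L | records$c_end > model$L | records$c_start > records$c_end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("mutation coordinates out of range: c.%d_%d (CDS length %d)",
                 records$c_start[i], records$c_end[i], model$L), call. = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    k <- records$kind[i]
    slice <- substr(model$cds, records$c_start[i], records$c_end[i])
    if (k == "substitution") {
      if (records$c_start[i] != records$c_end[i] ||
          nchar(records$ref[i]) != 1L || nchar(records$alt[i]) != 1L ||
          records$ref[i] == records$alt[i]) {
        stop("malformed substitution record at c.", records$c_start[i], call. = FALSE)
      }
      if (records$ref[i] != slice) {
        stop(sprintf("reference mismatch at c.%d: expected %s, got %s",
                     records$c_start[i], slice, records$ref[i]), call. = FALSE)
      }
    } else if (k %in% c("deletion", "duplication")) {
      if (records$ref[i] == "") {
        records$ref[i] <- slice
      } else if (records$ref[i] != slice) {
        stop(sprintf("reference mismatch at c.%d_%d: expected %s, got %s",
                     records$c_start[i], records$c_end[i], slice, records$ref[i]),
             call. = FALSE)
      }
      if (k == "deletion") records$alt[i] <- ""
      if (k == "duplication") records$alt[i] <- records$ref[i]
    } else if (k == "insertion") {
      if (records$c_end[i] != records$c_start[i] || nchar(records$alt[i]) < 1L) {
        stop("malformed insertion record at c.", records$c_start[i], call. = FALSE)
      }
      records$ref[i] <- ""
      .check_dna(records$alt[i], "inserted bases")
    }
  }
  records
}

#' Parse an HGVS-style c. descriptor
#'
#' Supported dialect (the four mutation kinds of the severity taxonomy):
#' `c.<p><R>><A>` (substitution), `c.<p>del` / `c.<p>_<q>del[<seq>]`
#' (deletion), `c.<p>dup` / `c.<p>_<q>dup` (duplication) and
#' `c.<p>_<p+1>ins<seq>` (insertion). Complex delins are unsupported and
#' raise an error rather than being coerced.
#'
#' @param text A single descriptor, e.g. `"c.76A>G"`.
#' @param model A [gene_model()] for reference validation.
#' @param case_id Optional case identifier carried into the record.
#' @return One-row mutation record data frame.
#' @export
parse_c_notation <- function(text, model, case_id = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  rx_sub <- "^c\\.([0-9]+)([ACGT])>([ACGT])$"
  rx_del <- "^c\\.([0-9]+)(?:_([0-9]+))?del([ACGT]*)$"
  rx_dup <- "^c\\.([0-9]+)(?:_([0-9]+))?dup$"
  rx_ins <- "^c\\.([0-9]+)_([0-9]+)ins([ACGT]+)$"
  rec <- if (grepl(rx_sub, txt)) {
    m <- regmatches(txt, regexec(rx_sub, txt))[[1L]]
    p <- as.integer(m[2L])
    .mutation_record(case_id, "substitution", p, p, m[3L], m[4L])
  } else if (grepl(rx_ins, txt)) {
    m <- regmatches(txt, regexec(rx_ins, txt))[[1L]]
    p <- as.integer(m[2L]); q <- as.integer(m[3L])
    if (q != p + 1L) stop("insertion anchor must be adjacent positions: ", txt,
                          call. = FALSE)
    .mutation_record(case_id, "insertion", p, p, "", m[4L])
  } else if (grepl(rx_del, txt)) {
    m <- regmatches(txt, regexec(rx_del, txt))[[1L]]
    p <- as.integer(m[2L])
    q <- if (m[3L] == "") p else as.integer(m[3L])
    .mutation_record(case_id, "deletion", p, q, m[4L], "")
  } else if (grepl(rx_dup, txt)) {
    m <- regmatches(txt, regexec(rx_dup, txt))[[1L]]
    p <- as.integer(m[2L])
    q <- if (m[3L] == "") p else as.integer(m[3L])
    .mutation_record(case_id, "duplication", p, q, "", "")
  } else {
    stop("cannot parse mutation descriptor: '", txt, "'", call. = FALSE)
  }
  validate_mutations(rec, model)
}

#' Format a mutation record as c. notation
#'
#' Inverse of [parse_c_notation()] on all four kinds; deletions include the
#' deleted sequence when it is 10 nt or shorter.
#'
#' @param record One-row mutation record.
#' @return Descriptor string.
#' @export
format_c_notation <- function(record) {
  stopifnot(nrow(record) == 1L)
  p <- record$c_start; q <- record$c_end
  switch(record$kind,
    substitution = sprintf("c.%d%s>%s", p, record$ref, record$alt),
    deletion = if (p == q) {
      sprintf("c.%ddel%s", p, record$ref)
    } else {
      sprintf("c.%d_%ddel%s", p, q,
              if (nchar(record$ref) <= 10L) record$ref else "")
    },
    duplication = if (p == q) sprintf("c.%ddup", p) else sprintf("c.%d_%ddup", p, q),
    insertion = sprintf("c.%d_%dins%s", p, p + 1L, record$alt),
    stop("unknown kind: ", record$kind, call. = FALSE)
  )
}

#' Read a per-case mutation table
#'
#' Accepts either a two-column TSV (`case_id`, `mutation` in c. notation) or
#' an explicit six-column TSV (`case_id`, `kind`, `c_start`, `c_end`, `ref`,
#' `alt`). Rows are validated against the model; per-case file order is
#' preserved; exact duplicate rows are kept but counted and reported via a
#' message and the `n_duplicates` attribute.
#'
#' @param path TSV path (tab-delimited, header, UTF-8; `.` or empty = missing).
#' @param model A [gene_model()].
#' @return Mutation record data frame (possibly zero rows) with attribute
#'   `n_duplicates`.
#' @export
read_mutation_table <- function(path, model) {
  if (!file.exists(path)) stop("mutation table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c(".", ""),
                          check.names = FALSE)
  if (all(c("case_id", "mutation") %in% names(df))) {
    recs <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      recs[[i]] <- tryCatch(
        parse_c_notation(df$mutation[i], model, case_id = df$case_id[i]),
        error = function(e) stop(sprintf("line %d: %s", i + 1L, conditionMessage(e)),
                                 call. = FALSE))
    }
    out <- do.call(rbind, recs)
  } else if (all(c("case_id", "kind", "c_start", "c_end", "ref", "alt") %in% names(df))) {
    out <- .mutation_record(df$case_id, df$kind,
                            as.integer(df$c_start), as.integer(df$c_end),
                            ifelse(is.na(df$ref), "", df$ref),
                            ifelse(is.na(df$alt), "", df$alt))
    out <- validate_mutations(out, model)
  } else {
    stop("unknown mutation table column set: ", paste(names(df), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(out)) out <- .mutation_record(character(0), character(0),
                                            integer(0), integer(0),
                                            character(0), character(0))
  ndup <- sum(duplicated(out))
  if (ndup > 0L) message(ndup, " exact duplicate mutation row(s) retained")
  attr(out, "n_duplicates") <- ndup
  out
}

#' Write a mutation table in the c.-notation dialect
#'
#' Mirror of [read_mutation_table()]: re-reading the written file reproduces
#' the records.
#'
#' @param records Mutation record data frame.
#' @param path Output TSV path.
#' @export
write_mutation_table <- function(records, path) {
  mut <- vapply(seq_len(nrow(records)),
                function(i) format_c_notation(records[i, , drop = FALSE]),
                character(1))
  df <- data.frame(case_id = records$case_id, mutation = mut,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_vocab <- list(
  sex = c("M", "F"),
  aas = c("I", "II", "III", "IV"),
  b_symptoms = c("present", "absent"),
  ldh_gt_uln = c("yes", "no"),
  ecog_gt1 = c("yes", "no"),
  en_gt1 = c("yes", "no"),
  morphology = c("CB", "IB", "ANA", "NOS"),
  chemo_class = c("ALL-like", "CHOP-like", "other", "none"),
  radiotherapy = c("yes", "no"),
  response = c("CR", "CRu", "nC/SD", "PR", "PD"),
  relapse = c("yes", "no"),
  coo = c("GCB", "ABC", "unclassified"),
  mbl = c("mBL", "non-mBL", "intermediate"),
  pap = c("BL-PAP", "PAP-1", "PAP-2", "PAP-3", "PAP-4", "Mind-L"),
  cc = c("BCR", "HR", "OxPhos")
)

#' Read a clinical/signature table
#'
#' Tab-delimited, header, `.` or empty = missing. Required column: `case_id`.
#' Recognized columns: `age`, `sex`, `aas`, `b_symptoms`, `ldh_gt_uln`,
#' `ecog_gt1`, `en_gt1`, `morphology`, `chemo_class`, `radiotherapy`,
#' `response`, `relapse`, `os_time`, `os_event`, and the signature labels
#' `coo`, `mbl`, `pap`, `cc`. Categorical columns are checked against their
#' closed vocabularies; `os_time` must be >= 0 and `os_event` in {0, 1}.
#'
#' @param path TSV path.
#' @return Data frame, one row per case.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c(".", ""),
                          check.names = FALSE)
  if (!"case_id" %in% names(df)) stop("clinical table missing case_id column",
                                      call. = FALSE)
  for (col in intersect(names(.clinical_vocab), names(df))) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% .clinical_vocab[[col]]
    if (any(bad)) {
      stop(sprintf("invalid %s value '%s' (allowed: %s)", col,
                   df[[col]][bad][1L],
                   paste(.clinical_vocab[[col]], collapse = ", ")), call. = FALSE)
    }
  }
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  if ("os_time" %in% names(df)) {
    df$os_time <- as.numeric(df$os_time)
    if (any(df$os_time < 0, na.rm = TRUE)) stop("negative os_time", call. = FALSE)
  }
  if ("os_event" %in% names(df)) {
    df$os_event <- as.integer(df$os_event)
    if (any(!df$os_event %in% c(0L, 1L), na.rm = TRUE)) {
      stop("os_event must be 0 or 1", call. = FALSE)
    }
  }
  df
}

#' Write a clinical table
#'
#' @param clinical Clinical data frame as returned by [read_clinical_table()].
#' @param path Output TSV path.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- clinical
  for (col in names(out)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- "."
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' International prognostic index with missing-as-absent rule
#'
#' Sum of five binary adverse factors (age >= 60, LDH > ULN, ECOG > 1,
#' Ann Arbor III/IV, extranodal sites > 1); a missing factor counts as absent
#' (0), the pessimistic-scoring convention for incomplete baseline data.
#'
#' @param age60,ldh,ecog,aas34,en Flags: logical, `"yes"`/`"no"`, or `NA`.
#' @return Integer vector of scores in 0..5.
#' @export
compute_ipi <- function(age60, ldh, ecog, aas34, en) {
  f <- function(x) {
    if (is.character(x)) x <- x == "yes"
    v <- as.integer(x)
    v[is.na(v)] <- 0L
    v
  }
  f(age60) + f(ldh) + f(ecog) + f(aas34) + f(en)
}

#' Encode 0/1 regression covariates from clinical records and subtype calls
#'
#' Encodings (value set to 1): age >= 60; LDH > ULN; ECOG > 1; Ann Arbor
#' III/IV; extranodal sites > 1; B symptoms present; immunoblastic morphology;
#' non-GCB cell of origin; non-mBL; non-PAP-1; non-BCR; IPI >= 2; and the
#' mutation-status indicators (`socs1_mut`, `socs1_major`, `socs1_minor`).
#' A covariate is NA when its source field is missing — no value is invented —
#' except `ipi2`, which uses [compute_ipi()]'s missing-as-absent rule.
#'
#' @param clinical Clinical data frame (see [read_clinical_table()]).
#' @param subtype Subtype call data frame with `case_id` and `call`
#'   (see [classify_cohort()]); matched by `case_id`.
#' @return Data frame of covariates, one row per clinical row.
#' @export
encode_covariates <- function(clinical, subtype) {
  yn <- function(x) ifelse(is.na(x), NA_integer_, as.integer(x == "yes"))
  get0c <- function(col) if (col %in% names(clinical)) clinical[[col]] else
    rep(NA_character_, nrow(clinical))
  age <- if ("age" %in% names(clinical)) clinical$age else rep(NA_real_, nrow(clinical))
  aas <- get0c("aas")
  cov <- data.frame(
    case_id = clinical$case_id,
    age60 = ifelse(is.na(age), NA_integer_, as.integer(age >= 60)),
    ldh = yn(get0c("ldh_gt_uln")),
    ecog = yn(get0c("ecog_gt1")),
    aas34 = ifelse(is.na(aas), NA_integer_, as.integer(aas %in% c("III", "IV"))),
    en = yn(get0c("en_gt1")),
    bsym = ifelse(is.na(get0c("b_symptoms")), NA_integer_,
                  as.integer(get0c("b_symptoms") == "present")),
    ib = ifelse(is.na(get0c("morphology")), NA_integer_,
                as.integer(get0c("morphology") == "IB")),
    non_gcb = ifelse(is.na(get0c("coo")), NA_integer_,
                     as.integer(get0c("coo") != "GCB")),
    non_mbl = ifelse(is.na(get0c("mbl")), NA_integer_,
                     as.integer(get0c("mbl") != "mBL")),
    non_pap1 = ifelse(is.na(get0c("pap")), NA_integer_,
                      as.integer(get0c("pap") != "PAP-1")),
    non_bcr = ifelse(is.na(get0c("cc")), NA_integer_,
                     as.integer(get0c("cc") != "BCR")),
    stringsAsFactors = FALSE
  )
  cov$ipi2 <- as.integer(compute_ipi(cov$age60 == 1L, cov$ldh == 1L,
                                     cov$ecog == 1L, cov$aas34 == 1L,
                                     cov$en == 1L) >= 2L)
  call <- subtype$call[match(clinical$case_id, subtype$case_id)]
  cov$socs1_mut <- ifelse(is.na(call), NA_integer_,
                          as.integer(call %in% c("major", "minor")))
  cov$socs1_major <- ifelse(is.na(call), NA_integer_, as.integer(call == "major"))
  cov$socs1_minor <- ifelse(is.na(call), NA_integer_, as.integer(call == "minor"))
  cov
}
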