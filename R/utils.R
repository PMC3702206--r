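# Internal helpers shared across modules.

#' @importFrom Biostrings GENETIC_CODE
NULL

# Codon -> amino-acid lookup (one-letter, "*" for stop), from the standard code.
.codon_table <- function() {
  Biostrings::GENETIC_CODE
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the ACGT alphabet.
#'
#' @param seq A single DNA string (A/C/G/T, case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("acgtACGT", "TGCATGCA", seq)
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

.check_dna <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop(sprintf("non-ACGT character '%s' in %s at position %d",
                 chars[bad[1L]], what, bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Translate a coding sequence
#'
#' Translates an in-frame coding DNA sequence to protein using the standard
#' genetic code; stop codons become `*`.
#'
#' @param cds Coding DNA string, length divisible by 3.
#' @return Single-letter amino-acid string (including any `*`).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  tab <- .codon_table()
  aa <- unname(tab[codons])
  if (anyNA(aa)) stop("untranslatable codon: ", codons[which(is.na(aa))[1L]],
                      call. = FALSE)
  paste(aa, collapse = "")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}
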