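# Gene reference frame: coding sequence, protein-domain intervals,
# transcript <-> CDS coordinate arithmetic, and primer/amplicon placement.

#' Construct a validated gene model
#'
#' A gene model bundles a coding sequence with an ordered set of protein-domain
#' intervals and names the domains treated as C-terminal for severity calling.
#' All coordinates are 1-based, fully closed intervals: a domain spanning
#' amino acids `[aa_start, aa_end]` occupies CDS nucleotides
#' `[3*(aa_start-1)+1, 3*aa_end]`.
#'
#' @param gene_symbol Gene symbol (e.g. `"SOCS1"`).
#' @param cds Coding sequence over A/C/G/T. Must start with `ATG` and have
#'   length divisible by 3. With `strict = TRUE` it must additionally end in a
#'   stop codon and contain no internal in-frame stop; with `strict = FALSE`
#'   those two conditions raise a warning only (user-supplied references may
#'   legitimately carry truncated or partial ORFs).
#' @param domains Data frame with columns `name`, `aa_start`, `aa_end`,
#'   `is_cterminal` (logical). Domains may overlap or nest; they are never
#'   merged.
#' @param cterm_names Character vector of domain names forming the C-terminal
#'   set used for major-subtype calling. Defaults to the `is_cterminal`-flagged
#'   domains.
#' @param upstream_context,downstream_context Optional flanking sequence
#'   immediately 5'/3' of the CDS, used so motif scans can cross the CDS edges.
#' @param cds_offset_in_exon2 Transcript (exon-2) position of the first CDS
#'   base (the `A` of `ATG`); 705 for the packaged SOCS1 model.
#' @param strict Enforce the stop-codon invariants as errors (default `TRUE`).
#' @return An object of class `gene_model`: a list with elements
#'   `gene_symbol`, `cds`, `L` (CDS length), `protein_length`, `domains`
#'   (with derived `nt_start`/`nt_end`), `cterm_names`, contexts and
#'   `cds_offset_in_exon2`.
#' @export
gene_model <- function(gene_symbol, cds, domains,
                       cterm_names = NULL,
                       upstream_context = "", downstream_context = "",
                       cds_offset_in_exon2 = NA_integer_,
                       strict = TRUE) {
  cds <- toupper(cds)
  .check_dna(cds, "cds")
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3", call. = FALSE)
  if (substr(cds, 1L, 3L) != "ATG") stop("CDS does not start with ATG", call. = FALSE)
  prot <- translate_cds(cds)
  n_aa <- nchar(prot)
  stops <- which(strsplit(prot, "", fixed = TRUE)[[1L]] == "*")
  complain <- if (strict) stop else warning
  if (substr(prot, n_aa, n_aa) != "*") {
    complain("CDS does not end in a stop codon", call. = FALSE)
  }
  if (any(stops < n_aa)) {
    complain("CDS contains an internal in-frame stop codon at codon ",
             stops[stops < n_aa][1L], call. = FALSE)
  }
  protein_length <- n_aa - as.integer(substr(prot, n_aa, n_aa) == "*")

  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  req <- c("name", "aa_start", "aa_end", "is_cterminal")
  miss <- setdiff(req, names(domains))
  if (length(miss) > 0L) stop("domain table missing field(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  domains$aa_start <- as.integer(domains$aa_start)
  domains$aa_end <- as.integer(domains$aa_end)
  domains$is_cterminal <- as.logical(domains$is_cterminal)
  if (any(domains$aa_start < 1L | domains$aa_start > domains$aa_end)) {
    stop("domain with aa_start < 1 or aa_start > aa_end", call. = FALSE)
  }
  if (any(domains$aa_end > protein_length)) {
    bad <- domains$name[domains$aa_end > protein_length][1L]
    stop(sprintf("domain '%s' extends beyond the protein (length %d)",
                 bad, protein_length), call. = FALSE)
  }
  domains$nt_start <- 3L * (domains$aa_start - 1L) + 1L
  domains$nt_end <- 3L * domains$aa_end

  if (is.null(cterm_names)) cterm_names <- domains$name[domains$is_cterminal]
  if (!all(cterm_names %in% domains$name)) {
    stop("cterm_names not all present among domain names: ",
         paste(setdiff(cterm_names, domains$name), collapse = ", "),
         call. = FALSE)
  }
  upstream_context <- toupper(upstream_context)
  downstream_context <- toupper(downstream_context)
  if (nzchar(upstream_context)) .check_dna(upstream_context, "upstream_context")
  if (nzchar(downstream_context)) .check_dna(downstream_context, "downstream_context")

  structure(list(
    gene_symbol = gene_symbol,
    cds = cds,
    L = L,
    protein = prot,
    protein_length = protein_length,
    domains = domains,
    cterm_names = cterm_names,
    upstream_context = upstream_context,
    downstream_context = downstream_context,
    cds_offset_in_exon2 = as.integer(cds_offset_in_exon2)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: CDS %d nt (%d aa), %d domains (C-terminal: %s)\n",
              x$gene_symbol, x$L, x$protein_length, nrow(x$domains),
              paste(x$cterm_names, collapse = ", ")))
  invisible(x)
}

# Read the first record of a FASTA file as an uppercase DNA string (U -> T).
.read_first_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seq <- toupper(as.character(set[[1L]]))
  gsub("U", "T", seq, fixed = TRUE)
}

#' Load a gene model from a JSON descriptor
#'
#' The JSON schema is
#' `{gene_symbol, cds, cds_offset_in_exon2, domains: [{name, aa_start, aa_end,
#' is_cterminal}], upstream_context, downstream_context}` where `cds` is
#' either an inline sequence string or `{"fasta": "file.fa"}` referencing a
#' FASTA file relative to the JSON file (first record used, uppercased,
#' U normalized to T).
#'
#' @param model_path Path to the JSON descriptor.
#' @param strict Passed to [gene_model()]; defaults to `FALSE` for
#'   user-supplied references (stop-codon problems warn instead of erroring).
#' @return A validated [gene_model()].
#' @export
load_gene_model <- function(model_path, strict = FALSE) {
  if (!file.exists(model_path)) stop("gene model file not found: ", model_path,
                                     call. = FALSE)
  js <- jsonlite::fromJSON(model_path, simplifyVector = TRUE)
  for (field in c("gene_symbol", "cds", "domains")) {
    if (is.null(js[[field]])) {
      stop("gene model JSON missing required field '", field, "'", call. = FALSE)
    }
  }
  cds <- js$cds
  if (is.list(cds)) {
    if (is.null(cds$fasta)) stop("cds object must carry a 'fasta' field", call. = FALSE)
    cds <- .read_first_fasta(file.path(dirname(model_path), cds$fasta))
  }
  gene_model(
    gene_symbol = js$gene_symbol,
    cds = cds,
    domains = js$domains,
    upstream_context = if (is.null(js$upstream_context)) "" else js$upstream_context,
    downstream_context = if (is.null(js$downstream_context)) "" else js$downstream_context,
    cds_offset_in_exon2 = if (is.null(js$cds_offset_in_exon2)) NA_integer_ else js$cds_offset_in_exon2,
    strict = strict
  )
}

#' The packaged SOCS1-like gene model
#'
#' Loads the synthetic SOCS1-like reference shipped with the package: a
#' 636-bp coding region (211-aa protein) with the SOCS1 domain layout
#' (SH3, JAK region containing KIR and SH2, NLS, SOCS box) and transcript
#' offset 705. The sequence and the exact domain boundaries are synthetic
#' stand-ins (the domain identities are real, their printed boundaries are
#' not); the JSON fixture under `inst/extdata` is editable and documents this.
#'
#' @return A [gene_model()].
#' @export
socs1_model <- function() {
  load_gene_model(system.file("extdata", "socs1_synthetic_gene_model.json",
                              package = "socs1mut", mustWork = TRUE),
                  strict = TRUE)
}

#' Convert a transcript (exon-2) position to a CDS coordinate
#'
#' `c = pos - cds_offset_in_exon2 + 1` when the result lies within the CDS;
#' positions outside are reported with a UTR flag and distance instead of an
#' error. For the SOCS1 offsets, transcript position 705 is c.1 and 1340 is
#' c.636.
#'
#' @param pos Integer vector of transcript positions (>= 1).
#' @param model A [gene_model()] with `cds_offset_in_exon2` set.
#' @return Data frame with columns `pos`, `region` (`"CDS"`, `"5'UTR"`,
#'   `"3'UTR"`), `c_pos` (NA outside the CDS) and `distance` (0 inside; number
#'   of nucleotides beyond the nearest CDS edge otherwise).
#' @export
transcript_to_cds_position <- function(pos, model) {
  stopifnot(inherits(model, "gene_model"))
  off <- model$cds_offset_in_exon2
  if (is.na(off)) stop("model has no cds_offset_in_exon2", call. = FALSE)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("transcript positions must be >= 1", call. = FALSE)
  cc <- pos - off + 1L
  region <- ifelse(cc < 1L, "5'UTR", ifelse(cc > model$L, "3'UTR", "CDS"))
  data.frame(
    pos = pos,
    region = region,
    c_pos = ifelse(region == "CDS", cc, NA_integer_),
    distance = ifelse(region == "5'UTR", 1L - cc,
               ifelse(region == "3'UTR", cc - model$L, 0L))
  )
}

#' Convert a CDS coordinate back to a transcript position
#'
#' Exact inverse of [transcript_to_cds_position()] on `[1, L]`.
#'
#' @param c_pos Integer vector of CDS positions in `[1, L]`.
#' @param model A [gene_model()].
#' @return Integer vector of transcript positions.
#' @export
cds_to_transcript_position <- function(c_pos, model) {
  stopifnot(inherits(model, "gene_model"))
  c_pos <- as.integer(c_pos)
  if (any(c_pos < 1L | c_pos > model$L)) {
    stop("CDS position outside [1, ", model$L, "]", call. = FALSE)
  }
  c_pos + model$cds_offset_in_exon2 - 1L
}

#' Place a primer pair on a template and report the PCR product
#'
#' Exact matching only: the forward primer is matched as given on the template
#' strand; the reverse primer is matched as its reverse complement. The product
#' interval is 1-based inclusive, from the first base of the forward match to
#' the last base of the reverse-complement match. With multiple placements the
#' leftmost forward match is paired with the nearest downstream reverse match
#' and a multiplicity warning is raised.
#'
#' @param template Template DNA string.
#' @param fwd_primer,rev_primer Primer sequences (reverse primer given 5'->3'
#'   on the opposite strand, as primers are ordered).
#' @return List with `start`, `end`, `length`.
#' @export
find_amplicon <- function(template, fwd_primer, rev_primer) {
  template <- toupper(template)
  fwd_primer <- toupper(fwd_primer)
  rev_primer <- toupper(rev_primer)
  stopifnot(nzchar(fwd_primer), nzchar(rev_primer))
  fhits <- .all_fixed_matches(template, fwd_primer)
  if (length(fhits) == 0L) stop("primer absent: forward", call. = FALSE)
  rc <- revcomp(rev_primer)
  rhits <- .all_fixed_matches(template, rc)
  if (length(rhits) == 0L) stop("primer absent: reverse", call. = FALSE)
  if (length(fhits) > 1L || length(rhits) > 1L) {
    warning("multiple primer placements; using leftmost forward with nearest downstream reverse",
            call. = FALSE)
  }
  fstart <- fhits[1L]
  rends <- rhits + nchar(rc) - 1L
  down <- rhits[rhits >= fstart + nchar(fwd_primer)]
  if (length(down) == 0L) stop("no product: reverse-primer match upstream of forward match",
                               call. = FALSE)
  rstart <- min(down)
  rend <- rstart + nchar(rc) - 1L
  list(start = fstart, end = rend, length = rend - fstart + 1L)
}

.all_fixed_matches <- function(subject, query) {
  m <- gregexpr(query, subject, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}
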