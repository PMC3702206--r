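# Synthetic gene models and cohorts with planted truth: mutation catalogs
# with tunable hypermutation-motif bias, subtype-conditional signature
# labels, and proportional-hazards survival times.

#' Default SOCS1-like domain layout
#'
#' Stand-in boundaries for a 211-aa protein: SH3 10-40, JAK region 56-155
#' containing KIR 56-66 and SH2 79-155, NLS 159-171, SOCS box 172-211.
#' NLS and SOCS box form the C-terminal set.
#'
#' @return Domain data frame usable with [gene_model()].
#' @export
socs1_domain_layout <- function() {
  data.frame(
    name = c("SH3", "JAK", "KIR", "SH2", "NLS", "SOCS box"),
    aa_start = c(10L, 56L, 56L, 79L, 159L, 172L),
    aa_end = c(40L, 155L, 66L, 155L, 171L, 211L),
    is_cterminal = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters
#'
#' Defaults emulate the study conditions of the reference cohort: 154 cases,
#' 16% mutant prevalence, an even major/minor split among mutants, 1-18 point
#' mutations per mutant case (truncated geometric, mean about 4), and 41%
#' of substitutions placed on hypermutation-mutable positions. Signature
#' conditionals default to the published per-subtype label proportions.
#' The log hazard ratios are free simulation parameters (the individual-level
#' survival data behind the published curves are not available), defaulting
#' to -1.2 for major (protective) and +1.0 for minor (adverse).
#'
#' @param n_cases Cohort size.
#' @param mutant_prevalence P(case is mutant).
#' @param p_major_given_mutant P(major | mutant).
#' @param mut_count_range Integer range of point-mutation counts per mutant
#'   case.
#' @param mut_count_mean Target mean of the truncated-geometric count.
#' @param shm_target_prob Probability that a simulated substitution lands on
#'   a mutable motif position (the complement is drawn from non-mutable
#'   positions).
#' @param signature_conditionals Nested list `sig -> subtype -> named
#'   probability vector`; see [default_signature_conditionals()].
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @param log_hr_major,log_hr_minor Planted log hazard ratios.
#' @param censoring_rate Target overall censoring fraction (independent
#'   uniform censoring).
#' @param seed RNG seed (mandatory).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_cases = 154L,
                       mutant_prevalence = 0.16,
                       p_major_given_mutant = 0.5,
                       mut_count_range = c(1L, 18L),
                       mut_count_mean = 4,
                       shm_target_prob = 0.41,
                       signature_conditionals = default_signature_conditionals(),
                       baseline_hazard = 0.02,
                       log_hr_major = -1.2,
                       log_hr_minor = 1.0,
                       censoring_rate = 0.3,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(mutant_prevalence >= 0, mutant_prevalence <= 1,
            p_major_given_mutant >= 0, p_major_given_mutant <= 1,
            shm_target_prob >= 0, shm_target_prob <= 1,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0,
            mut_count_range[1L] >= 1L, mut_count_range[2L] >= mut_count_range[1L])
  for (sig in names(signature_conditionals)) {
    for (st in names(signature_conditionals[[sig]])) {
      p <- signature_conditionals[[sig]][[st]]
      if (abs(sum(p) - 1) > 1e-8) {
        stop("signature conditional does not sum to 1: ", sig, "/", st,
             call. = FALSE)
      }
    }
  }
  structure(list(
    n_cases = as.integer(n_cases),
    mutant_prevalence = mutant_prevalence,
    p_major_given_mutant = p_major_given_mutant,
    mut_count_range = as.integer(mut_count_range),
    mut_count_mean = mut_count_mean,
    shm_target_prob = shm_target_prob,
    signature_conditionals = signature_conditionals,
    baseline_hazard = baseline_hazard,
    log_hr_major = log_hr_major,
    log_hr_minor = log_hr_minor,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Published per-subtype signature label proportions
#'
#' Conditional distributions of the four expression-signature labels (COO,
#' mBL, PAP, CC) given subtype, proportional to the published per-subtype
#' counts: e.g. all major cases carry the GCB cell-of-origin label.
#'
#' @return Nested list `signature -> subtype -> named probability vector`.
#' @export
default_signature_conditionals <- function() {
  pr <- function(x) x / sum(x)
  list(
    coo = list(
      wild_type = pr(c(GCB = 51, ABC = 47, unclassified = 32)),
      major = c(GCB = 1),
      minor = pr(c(GCB = 7, ABC = 2, unclassified = 3))
    ),
    mbl = list(
      wild_type = pr(c("mBL" = 9, "non-mBL" = 90, "intermediate" = 31)),
      major = pr(c("mBL" = 1, "non-mBL" = 9, "intermediate" = 2)),
      minor = pr(c("non-mBL" = 10, "intermediate" = 2))
    ),
    pap = list(
      wild_type = pr(c("BL-PAP" = 10, "PAP-1" = 25, "PAP-2" = 27,
                       "PAP-3" = 21, "PAP-4" = 9, "Mind-L" = 38)),
      major = pr(c("PAP-1" = 7, "PAP-4" = 1, "Mind-L" = 4)),
      minor = pr(c("PAP-1" = 5, "PAP-2" = 1, "PAP-3" = 3, "Mind-L" = 3))
    ),
    cc = list(
      wild_type = pr(c(BCR = 66, HR = 38, OxPhos = 16)),
      major = pr(c(BCR = 5, HR = 4)),
      minor = pr(c(BCR = 5, HR = 4, OxPhos = 2))
    )
  )
}

#' Generate a random valid gene model
#'
#' Random coding sequence of the requested length: starts with ATG, ends with
#' a stop codon, and has no internal in-frame stop (sense codons are sampled
#' directly). Domains are placed per the layout.
#'
#' @param length CDS length in nt (divisible by 3); default 636.
#' @param domain_layout Domain data frame; default [socs1_domain_layout()].
#' @param seed RNG seed.
#' @param upstream_context,downstream_context Lengths (nt) of random flanking
#'   context to attach; default 20 each.
#' @return A [gene_model()].
#' @export
generate_reference <- function(length = 636L, domain_layout = socs1_domain_layout(),
                               seed = 1L, upstream_context = 20L,
                               downstream_context = 20L) {
  length <- as.integer(length)
  if (length %% 3L != 0L) stop("length must be divisible by 3", call. = FALSE)
  n_codons <- length %/% 3L
  if (n_codons < 2L) stop("length too short", call. = FALSE)
  max_aa <- max(domain_layout$aa_end)
  if (n_codons - 1L < max_aa) {
    stop(sprintf("impossible layout: protein length %d < last domain end %d",
                 n_codons - 1L, max_aa), call. = FALSE)
  }
  tab <- .codon_table()
  sense <- names(tab)[tab != "*"]
  .with_seed(seed, {
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    cds <- paste0("ATG", paste(body, collapse = ""), sample(.stop_codons, 1L))
    up <- paste(sample(c("A", "C", "G", "T"), upstream_context, replace = TRUE),
                collapse = "")
    down <- paste(sample(c("A", "C", "G", "T"), downstream_context, replace = TRUE),
                  collapse = "")
    gene_model("SYNTH1", cds, domain_layout,
               upstream_context = up, downstream_context = down,
               cds_offset_in_exon2 = 705L, strict = TRUE)
  })
}

# Truncated geometric on [lo, hi] with untruncated mean `mean` (support
# starting at lo); resamples values beyond hi.
.r_trunc_geom <- function(n, lo, hi, mean) {
  p <- 1 / (mean - lo + 1)
  out <- lo + stats::rgeom(n, p)
  while (any(out > hi)) {
    k <- out > hi
    out[k] <- lo + stats::rgeom(sum(k), p)
  }
  out
}

# Sample one substitution at CDS position p that is not a stop gain.
.safe_substitution <- function(case_id, p, model) {
  ref <- substr(model$cds, p, p)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  ok <- vapply(alts, function(a) {
    is.na(.stop_gain_codon(.mutation_record(case_id, "substitution", p, p, ref, a),
                           model))
  }, logical(1))
  alts <- alts[ok]
  if (length(alts) == 0L) return(NULL)
  .mutation_record(case_id, "substitution", p, p, ref, sample(alts, 1L))
}

# Sample substitution positions: mutable motif position with prob theta,
# otherwise a non-mutable position (both uniform within their class).
.sample_positions <- function(k, theta, mut_pos, L) {
  non_mut <- setdiff(seq_len(L), mut_pos)
  at <- stats::runif(k) < theta
  pos <- integer(k)
  if (any(at)) pos[at] <- sample(mut_pos, sum(at), replace = FALSE)
  if (any(!at)) pos[!at] <- sample(non_mut, sum(!at), replace = FALSE)
  pos
}

# One truncating event guaranteed to impact the C-terminal set under the
# aggressive weighting: a stop gain or a frameshift deletion strictly 5' of
# the first C-terminal domain.
.truncating_event <- function(case_id, model) {
  cterm_start <- min(model$domains$nt_start[model$domains$name %in% model$cterm_names])
  # candidate stop-gain positions (codons 2 .. cterm_start codon - 1)
  if (stats::runif(1) < 0.5) {
    for (attempt in 1:30) {
      p <- sample(4:(cterm_start - 1L), 1L)
      ref <- substr(model$cds, p, p)
      for (a in sample(setdiff(c("A", "C", "G", "T"), ref))) {
        rec <- .mutation_record(case_id, "substitution", p, p, ref, a)
        if (!is.na(.stop_gain_codon(rec, model))) return(rec)
      }
    }
  }
  # frameshift deletion of 1 or 2 nt
  w <- sample(1:2, 1L)
  p <- sample(4:(cterm_start - w), 1L)
  .mutation_record(case_id, "deletion", p, p + w - 1L,
                   substr(model$cds, p, p + w - 1L), "")
}

# Uniform-censoring horizon giving approximately the target censoring
# fraction for the exponential mixture of subtypes.
.censoring_horizon <- function(params) {
  lam0 <- params$baseline_hazard
  pm <- params$mutant_prevalence
  w <- c(1 - pm, pm * params$p_major_given_mutant,
         pm * (1 - params$p_major_given_mutant))
  lams <- lam0 * exp(c(0, params$log_hr_major, params$log_hr_minor))
  q <- params$censoring_rate
  if (q <= 0) return(Inf)
  f <- function(u) sum(w * (1 - exp(-lams * u)) / (lams * u)) - q
  stats::uniroot(f, lower = 1e-6, upper = 1e6)$root
}

#' Generate a synthetic cohort with planted truth
#'
#' Draws mutant status, subtype, mutation catalogs (major cases carry at
#' least one truncating event reaching the C-terminal domains by
#' construction; minor cases carry only non-foreshortening substitutions,
#' placed on mutable motif positions with probability `shm_target_prob`),
#' subtype-conditional signature labels, basic clinical covariates, and
#' exponential proportional-hazards survival times with independent uniform
#' censoring. Fully deterministic under `params$seed`.
#'
#' @param params A [sim_params()].
#' @param model A [gene_model()]; default [generate_reference()] derived from
#'   the same seed.
#' @return List of class `synthetic_cohort`: `mutations` (record data frame),
#'   `clinical` (clinical/signature/survival data frame), `truth` (per-case
#'   planted subtype and SHM flags plus the parameters), `model`.
#' @export
generate_cohort <- function(params, model = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(model)) model <- generate_reference(seed = params$seed)
  mut_pos <- mutable_positions(model)
  if (params$shm_target_prob > 0 && length(mut_pos) == 0L) {
    stop("infeasible parameters: shm_target_prob > 0 but reference has no mutable motif positions",
         call. = FALSE)
  }
  n <- params$n_cases
  .with_seed(params$seed, {
    ids <- sprintf("SIM-%04d", seq_len(n))
    is_mut <- stats::runif(n) < params$mutant_prevalence
    subtype <- ifelse(!is_mut, "wild_type",
                      ifelse(stats::runif(n) < params$p_major_given_mutant,
                             "major", "minor"))
    mut_list <- list()
    shm_flags <- list()
    for (i in which(is_mut)) {
      k <- .r_trunc_geom(1L, params$mut_count_range[1L],
                         params$mut_count_range[2L], params$mut_count_mean)
      n_subst <- if (subtype[i] == "major") k - 1L else k
      recs <- NULL
      flags <- logical(0)
      if (n_subst > 0L) {
        pos <- .sample_positions(n_subst, params$shm_target_prob, mut_pos, model$L)
        for (p in pos) {
          r <- .safe_substitution(ids[i], p, model)
          if (!is.null(r)) {
            recs <- rbind(recs, r)
            flags <- c(flags, p %in% mut_pos)
          }
        }
      }
      if (subtype[i] == "major") {
        recs <- rbind(recs, .truncating_event(ids[i], model))
        flags <- c(flags, NA)
      }
      mut_list[[ids[i]]] <- recs
      shm_flags[[ids[i]]] <- flags
    }
    mutations <- do.call(rbind, mut_list)
    if (is.null(mutations)) {
      mutations <- .mutation_record(character(0), character(0), integer(0),
                                    integer(0), character(0), character(0))
    }
    rownames(mutations) <- NULL

    draw_sig <- function(sig) {
      vapply(subtype, function(st) {
        p <- params$signature_conditionals[[sig]][[st]]
        sample(names(p), 1L, prob = p)
      }, character(1), USE.NAMES = FALSE)
    }
    age <- pmin(93, pmax(3, round(stats::rnorm(n, 60, 16))))
    lam <- params$baseline_hazard * exp(
      ifelse(subtype == "major", params$log_hr_major,
             ifelse(subtype == "minor", params$log_hr_minor, 0)))
    T_ev <- stats::rexp(n, rate = lam)
    cmax <- .censoring_horizon(params)
    C <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
    clinical <- data.frame(
      case_id = ids,
      age = age,
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4)),
      aas = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.20, 0.24, 0.28, 0.28)),
      b_symptoms = sample(c("present", "absent", NA), n, replace = TRUE,
                          prob = c(0.41, 0.54, 0.05)),
      ldh_gt_uln = sample(c("yes", "no", NA), n, replace = TRUE,
                          prob = c(0.38, 0.52, 0.10)),
      ecog_gt1 = sample(c("yes", "no", NA), n, replace = TRUE,
                        prob = c(0.24, 0.66, 0.10)),
      en_gt1 = sample(c("yes", "no", NA), n, replace = TRUE,
                      prob = c(0.19, 0.71, 0.10)),
      morphology = sample(c("CB", "NOS", "IB", "ANA"), n, replace = TRUE,
                          prob = c(0.45, 0.40, 0.10, 0.05)),
      chemo_class = sample(c("CHOP-like", "ALL-like", "other", "none"), n,
                           replace = TRUE, prob = c(0.65, 0.12, 0.13, 0.10)),
      radiotherapy = sample(c("yes", "no"), n, replace = TRUE,
                            prob = c(0.25, 0.75)),
      coo = draw_sig("coo"),
      mbl = draw_sig("mbl"),
      pap = draw_sig("pap"),
      cc = draw_sig("cc"),
      os_time = round(pmin(T_ev, C), 3),
      os_event = as.integer(T_ev <= C),
      stringsAsFactors = FALSE
    )
    truth <- list(
      params = unclass(params),
      cases = data.frame(case_id = ids, subtype = subtype,
                         stringsAsFactors = FALSE),
      shm_targeted = shm_flags
    )
    structure(list(mutations = mutations, clinical = clinical,
                   truth = truth, model = model),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort to disk
#'
#' Emits the mutation TSV and clinical TSV in exactly the dialects consumed
#' by [read_mutation_table()] and [read_clinical_table()], plus a
#' `truth.json` with the planted subtypes and parameters. Byte-identical
#' across reruns of the same generated cohort.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mut_path <- file.path(dir, "mutations.tsv")
  clin_path <- file.path(dir, "clinical.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_mutation_table(cohort$mutations, mut_path)
  write_clinical_table(cohort$clinical, clin_path)
  truth <- cohort$truth
  truth$shm_targeted <- lapply(truth$shm_targeted, as.logical)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(mutations = mut_path, clinical = clin_path, truth = truth_path))
}
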