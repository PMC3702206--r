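# Cohort-level statistics: crosstabs, exact contingency-table tests
# (hypergeometric 2x2 and Freeman-Halton r x c with a Monte Carlo fallback),
# domain frequency maps, Kaplan-Meier curves and Cox proportional-hazards
# fits.

#' Cross-tabulate two categorical variables
#'
#' Rows with a missing value in either variable are excluded pairwise (so
#' denominators vary by table, as in descriptive cohort tables).
#'
#' @param cohort Data frame.
#' @param row_variable,col_variable Column names.
#' @param row_levels,col_levels Optional label orders; defaults to order of
#'   appearance.
#' @return Integer matrix with named dimnames; attribute `n` carries the
#'   pairwise-complete denominator.
#' @export
build_crosstab <- function(cohort, row_variable, col_variable,
                           row_levels = NULL, col_levels = NULL) {
  for (v in c(row_variable, col_variable)) {
    if (!v %in% names(cohort)) stop("unknown variable: ", v, call. = FALSE)
  }
  r <- cohort[[row_variable]]
  c_ <- cohort[[col_variable]]
  keep <- !is.na(r) & !is.na(c_)
  r <- r[keep]; c_ <- c_[keep]
  if (is.null(row_levels)) row_levels <- unique(r)
  if (is.null(col_levels)) col_levels <- unique(c_)
  tab <- table(factor(r, levels = row_levels), factor(c_, levels = col_levels))
  m <- matrix(as.integer(tab), nrow = length(row_levels),
              dimnames = list(row_levels, col_levels))
  attr(m, "n") <- sum(keep)
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed the observed table's
#' (minimum-likelihood two-sided convention; ties guarded by a relative
#' tolerance of 1e-12).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1L, 1L], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

# log multivariate-hypergeometric probability of a table given fixed margins
.log_table_prob <- function(cells, row_sums, col_sums, N) {
  sum(lfactorial(row_sums)) + sum(lfactorial(col_sums)) -
    lfactorial(N) - sum(lfactorial(cells))
}

# Enumerate all r x c tables with the given margins, calling visit(cells)
# for each; aborts (returns FALSE) if more than max_tables are produced.
.enumerate_tables <- function(row_sums, col_sums, max_tables, visit) {
  r <- length(row_sums); cn <- length(col_sums)
  cells <- integer(r * cn)
  count <- 0L
  aborted <- FALSE
  rec <- function(i, row_rem, col_rem) {
    if (aborted) return()
    if (i > r) {
      count <<- count + 1L
      if (count > max_tables) { aborted <<- TRUE; return() }
      visit(cells)
      return()
    }
    fill_row <- function(j, rem) {
      if (aborted) return()
      if (j == cn) {
        if (rem <= col_rem[cn]) {
          cells[(i - 1L) * cn + cn] <<- rem
          col_rem[cn] <<- col_rem[cn] - rem
          rec(i + 1L, row_rem, col_rem)
          col_rem[cn] <<- col_rem[cn] + rem
        }
        return()
      }
      hi <- min(rem, col_rem[j])
      # feasibility prune: the rest of the row must fit into the remaining
      # column capacity, so v cannot leave more than that behind
      lo <- max(0L, rem - sum(col_rem[(j + 1L):cn]))
      if (lo > hi) return()
      for (v in lo:hi) {
        cells[(i - 1L) * cn + j] <<- v
        col_rem[j] <<- col_rem[j] - v
        fill_row(j + 1L, rem - v)
        col_rem[j] <<- col_rem[j] + v
        if (aborted) return()
      }
    }
    fill_row(1L, row_rem[i])
  }
  rec(1L, row_sums, col_sums)
  !aborted
}

#' Freeman-Halton exact test for an r x c table
#'
#' Exact two-sided p by recursive enumeration over all tables with the
#' observed margins when their number does not exceed `max_tables`; otherwise
#' a seeded Monte Carlo estimate over `B` random tables with the same margins
#' (`p = (r + 1) / (B + 1)`). All-zero rows/columns are dropped with a
#' warning; a table degenerate after dropping (fewer than 2 rows or columns)
#' returns p = 1. On a 2x2 input the exact path coincides with
#' [fisher_exact_2x2()].
#'
#' @param tab Matrix of non-negative integer counts, at least 2x2.
#' @param max_tables Enumeration cap (default 5e6).
#' @param B Monte Carlo replicates for the fallback path.
#' @param seed Seed for the Monte Carlo path.
#' @return List with `p`, `method` (`"exact"` or `"monte_carlo"`),
#'   `n_tables` (exact path) and `total_prob` (conservation check: sum of all
#'   enumerated table probabilities, = 1 up to float error).
#' @export
fisher_exact_rxc <- function(tab, max_tables = 5e6, B = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2",
                                             call. = FALSE)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s)", call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(list(p = 1, method = "degenerate", n_tables = NA_integer_,
                total_prob = NA_real_))
  }
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  lp_obs <- .log_table_prob(as.integer(t(tab)), rs, cs, N)
  # tolerance on the probability scale, relative
  thresh <- lp_obs + log1p(1e-12)
  acc_p <- 0; acc_tot <- 0; n_tab <- 0L
  visit <- function(cells) {
    lp <- .log_table_prob(cells, rs, cs, N)
    pr <- exp(lp)
    acc_tot <<- acc_tot + pr
    if (lp <= thresh) acc_p <<- acc_p + pr
    n_tab <<- n_tab + 1L
  }
  complete <- .enumerate_tables(rs, cs, max_tables, visit)
  if (complete) {
    return(list(p = min(acc_p, 1), method = "exact", n_tables = n_tab,
                total_prob = acc_tot))
  }
  # Monte Carlo fallback over random tables with fixed margins
  hits <- .with_seed(seed, {
    sims <- stats::r2dtable(B, rs, cs)
    sum(vapply(sims, function(s) {
      .log_table_prob(as.integer(t(s)), rs, cs, N) <= thresh
    }, logical(1)))
  })
  list(p = (hits + 1) / (B + 1), method = "monte_carlo",
       n_tables = NA_integer_, total_prob = NA_real_)
}

#' Per-domain mutation frequency map over mutated cases
#'
#' For each domain of the model, the fraction of mutated cases with a direct
#' hit, and with a hit under the conservative and aggressive downstream
#' weightings (direct or downstream). The conservative fraction never exceeds
#' the aggressive one; the band between them is the predicted spectrum of
#' downstream consequences.
#'
#' @param consequences Non-empty list of `case_consequence` objects for the
#'   mutated cases (see [cohort_consequences()]).
#' @param model A [gene_model()].
#' @return Data frame with `domain`, `fraction_direct`,
#'   `fraction_conservative`, `fraction_aggressive`.
#' @export
domain_frequency_map <- function(consequences, model) {
  consequences <- Filter(function(x) x$n_mutations > 0L, consequences)
  n <- length(consequences)
  if (n == 0L) stop("no mutated cases", call. = FALSE)
  doms <- model$domains$name
  frac <- function(field) {
    vapply(doms, function(d) {
      mean(vapply(consequences, function(cc) d %in% cc[[field]], logical(1)))
    }, numeric(1))
  }
  data.frame(domain = doms,
             fraction_direct = unname(frac("affected_direct")),
             fraction_conservative = unname(frac("affected_conservative")),
             fraction_aggressive = unname(frac("affected_aggressive")),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit curves
#'
#' Product-limit estimate per group; subjects censored at an event time are
#' counted at risk at that time (the standard convention).
#'
#' @param times Follow-up times (>= 0).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group Optional group labels; one curve per group.
#' @return Data frame with `group`, `time`, `n_risk`, `n_event`, `surv`
#'   (rows only at distinct observed times).
#' @export
km_fit <- function(times, events, group = NULL) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(times))
  fit <- survival::survfit(survival::Surv(times, events) ~ grp,
                           data = data.frame(times = times, events = events,
                                             grp = group))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1L], length(s$time)) else
    sub("^grp=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv, stringsAsFactors = FALSE)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model on a 0/1 covariate matrix by maximizing the partial
#' likelihood (Breslow tie handling by default; Efron available). Subjects
#' with any missing included covariate are dropped (complete-case), and the
#' number dropped is reported. A covariate constant after the complete-case
#' drop is non-identifiable and raises an error naming the column; a monotone
#' likelihood (complete separation) is flagged, not silently returned.
#'
#' @param covariates Data frame or matrix of numeric covariates (columns
#'   named).
#' @param times Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored); at least one
#'   event required.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List of class `cox_fit`: `coefficients` data frame (`term`,
#'   `log_hr`, `se`, `ci_low`, `ci_high`, `p`), `loglik`, `iterations`,
#'   `converged`, `flagged` (monotone-likelihood diagnostic), `n_used`,
#'   `n_dropped`, and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(covariates, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  X <- as.data.frame(covariates)
  if (ncol(X) == 0L) stop("no covariates", call. = FALSE)
  stopifnot(nrow(X) == length(times), length(times) == length(events))
  complete <- stats::complete.cases(X) & !is.na(times) & !is.na(events)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  times <- times[complete]; events <- events[complete]
  if (sum(events) < 1) stop("no events after complete-case filtering", call. = FALSE)
  for (col in names(X)) {
    if (length(unique(X[[col]])) < 2L) {
      stop("non-identifiable: covariate '", col, "' is constant", call. = FALSE)
    }
  }
  dat <- cbind(data.frame(.time = times, .event = events), X)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(sprintf("`%s`", names(X)), collapse = " + ")))
  flagged <- FALSE
  diag_msg <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE)) {
        flagged <<- TRUE
        diag_msg <<- c(diag_msg, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(abs(beta) > 15)) {
    flagged <- TRUE
    diag_msg <- c(diag_msg, "monotone likelihood suspected (|log HR| > 15)")
  }
  coefs <- data.frame(
    term = names(beta),
    log_hr = unname(beta),
    se = unname(se),
    ci_low = unname(beta - 1.96 * se),
    ci_high = unname(beta + 1.96 * se),
    p = unname(sm$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs,
                 loglik = fit$loglik[length(fit$loglik)],
                 iterations = fit$iter,
                 converged = !flagged,
                 flagged = flagged,
                 diagnostics = diag_msg,
                 n_used = sum(complete),
                 n_dropped = n_dropped,
                 ties = ties,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d (%d dropped), ties=%s, loglik=%.3f%s\n",
              x$n_used, x$n_dropped, x$ties, x$loglik,
              if (x$flagged) " [FLAGGED]" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Breslow partial log-likelihood at a given coefficient vector
#'
#' Direct evaluation of the Breslow partial likelihood, independent of the
#' fitting route; used for oracle checks of [cox_fit()] and exported because
#' it is handy for profiling a fit.
#'
#' @param beta Coefficient vector.
#' @param X Covariate matrix.
#' @param times,events Survival outcome.
#' @return Log partial likelihood (scalar).
#' @export
breslow_loglik <- function(beta, X, times, events) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}
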