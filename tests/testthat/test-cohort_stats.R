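# Crosstabs, exact tests, frequency maps, Kaplan-Meier and Cox fits.

test_that("crosstabs exclude missing values pairwise", {
  df <- data.frame(status = c("mut", "mut", "wt", "wt", "wt", "mut"),
                   label = c("A", "B", "A", NA, "B", "A"),
                   stringsAsFactors = FALSE)
  tab <- build_crosstab(df, "status", "label",
                        row_levels = c("wt", "mut"), col_levels = c("A", "B"))
  expect_equal(attr(tab, "n"), 5L)
  expect_equal(unname(tab["mut", ]), c(2L, 1L))
  expect_equal(sum(tab), 5)
  expect_error(build_crosstab(df, "nope", "label"), "unknown variable")
  empty <- build_crosstab(df[0, ], "status", "label",
                          row_levels = c("wt", "mut"), col_levels = c("A", "B"))
  expect_equal(sum(empty), 0)
})

test_that("the published mutant-case tallies reproduce from the fixture", {
  cases <- socs1_mutant_cases()
  counts <- socs1_cohort_counts()
  expect_equal(nrow(cases), counts$n_mutant)
  expect_equal(round(100 * counts$n_mutant / counts$n_total), 16)
  coo <- build_crosstab(cbind(cases, status = "mutant"), "status", "coo")
  expect_equal(unname(coo[1, "GCB"]), 19L)
  expect_equal(round(100 * coo[1, "GCB"] / sum(coo), 1), 79.2)
  expect_equal(round(marker_tally(cases, "bcl2")$percent, 1), 75.0)
  expect_equal(round(marker_tally(cases, "cd10")$percent, 1), 29.2)
  expect_equal(round(marker_tally(cases, "bcl6_fish")$percent, 1), 30.4)
  expect_equal(round(marker_tally(cases, "mum1")$percent, 1), 54.5)
})

test_that("2x2 exact test matches hand enumeration and the printed value", {
  # mutant x PAP-1 from the published signature table
  expect_equal(round(fisher_exact_2x2(matrix(c(12, 25, 12, 105), 2)), 3), 0.003)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1.0)
  # full enumeration over C(6,3) = 20 tables: extreme tables have prob 1/20
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  expect_error(fisher_exact_2x2(matrix(1, 3, 2)), "2x2")
})

test_that("2x2 exact test agrees with the standard implementation", {
  set.seed(101)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10, info = paste(tab, collapse = ","))
  }
})

test_that("r x c enumeration conserves probability and collapses to 2x2", {
  set.seed(111)
  for (i in 1:500) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- fisher_exact_rxc(tab)
    expect_equal(res$method, "exact")
    expect_lt(abs(res$total_prob - 1), 1e-9)
    expect_lt(abs(res$p - fisher_exact_2x2(tab)), 1e-12)
  }
})

test_that("r x c exact test matches the standard implementation on small tables", {
  set.seed(121)
  for (i in 1:25) {
    r <- sample(2:3, 1); cn <- sample(2:3, 1)
    tab <- matrix(rpois(r * cn, 4), r)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- fisher_exact_rxc(tab)
    expect_equal(res$p, fisher.test(tab)$p.value, tolerance = 1e-8)
    expect_lt(abs(res$total_prob - 1), 1e-9)
  }
  # published status-by-signature table (3 x 2): exact value from enumeration
  coo <- t(signature_status_table("coo"))
  res <- fisher_exact_rxc(coo)
  expect_equal(res$p, fisher.test(coo)$p.value, tolerance = 1e-8)
})

test_that("r x c handles degenerate margins and falls back to Monte Carlo", {
  tab <- rbind(c(5, 1), c(0, 0), c(2, 4))
  expect_warning(res <- fisher_exact_rxc(tab), "all-zero")
  expect_equal(res$p, fisher_exact_2x2(rbind(c(5, 1), c(2, 4))))
  big <- matrix(rpois(24, 60) + 20, 4)
  mc <- fisher_exact_rxc(big, max_tables = 1000, B = 400, seed = 7)
  expect_equal(mc$method, "monte_carlo")
  expect_true(mc$p > 0 && mc$p <= 1)
  mc2 <- fisher_exact_rxc(big, max_tables = 1000, B = 400, seed = 7)
  expect_identical(mc$p, mc2$p)
})

test_that("domain frequency maps match per-case brute force", {
  m <- socs1_model()
  ch <- generate_cohort(sim_params(n_cases = 60, seed = 17), m)
  mutated <- unique(ch$mutations$case_id)
  ccs <- cohort_consequences(ch$mutations, m, case_ids = mutated)
  fm <- domain_frequency_map(ccs, m)
  expect_true(all(fm$fraction_conservative <= fm$fraction_aggressive + 1e-12))
  expect_true(all(fm$fraction_direct >= 0 & fm$fraction_direct <= 1))
  # brute force one domain
  d <- "SOCS box"
  frac <- mean(vapply(ccs, function(cc) d %in% cc$affected_aggressive, logical(1)))
  expect_equal(fm$fraction_aggressive[fm$domain == d], frac)
  expect_error(domain_frequency_map(list(), m), "no mutated cases")
})

test_that("product-limit estimates match hand calculations", {
  # all censored: survival stays at 1
  km <- km_fit(c(2, 3, 5), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  # times (1 event, 2 censored, 3 event): S(1) = 2/3, S(3) = 0
  km2 <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # single subject, event: survival jumps 1 -> 0
  km3 <- km_fit(4, 1)
  expect_equal(km3$surv[km3$time == 4], 0)
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
  # no censoring: equals the empirical survival function exactly
  set.seed(131)
  t <- rexp(40)
  km4 <- km_fit(t, rep(1, 40))
  expect_equal(km4$surv, vapply(km4$time, function(u) mean(t > u), numeric(1)))
})

test_that("Cox fits maximize the partial likelihood (grid oracle)", {
  toys <- list(
    list(times = c(1, 2, 3, 4, 5, 6), events = c(1, 1, 1, 1, 1, 0),
         x = c(1, 0, 1, 0, 0, 1)),
    list(times = c(2, 2, 3, 5, 6, 7), events = c(1, 0, 1, 1, 0, 1),
         x = c(1, 0, 0, 1, 1, 0)),
    list(times = c(1, 1.5, 2, 2.5, 3, 4, 8, 9),
         events = c(1, 1, 0, 1, 1, 1, 0, 1),
         x = c(0, 1, 1, 0, 0, 1, 0, 1))
  )
  for (toy in toys) {
    fit <- cox_fit(data.frame(x = toy$x), toy$times, toy$events)
    b_grid <- oracle_grid_cox(toy$x, toy$times, toy$events)
    expect_equal(fit$coefficients$log_hr, b_grid, tolerance = 1e-4)
    # score condition via the package's own likelihood: the fitted beta is a
    # local maximum against small perturbations
    ll <- breslow_loglik(fit$coefficients$log_hr, matrix(toy$x), toy$times,
                         toy$events)
    for (eps in c(-1e-3, 1e-3)) {
      expect_gte(ll + 1e-8, breslow_loglik(fit$coefficients$log_hr + eps,
                                           matrix(toy$x), toy$times, toy$events))
    }
  }
})

test_that("Cox fitting validates inputs and flags degenerate fits", {
  expect_error(cox_fit(data.frame(x = c(1, 1, 1)), c(1, 2, 3), c(1, 1, 0)),
               "constant")
  expect_error(cox_fit(data.frame(x = c(0, 1)), c(1, 2), c(0, 0)), "no events")
  # complete separation: flagged, not silent
  t <- c(1, 2, 3, 4, 10, 11, 12, 13)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- suppressWarnings(cox_fit(data.frame(x = x), t, rep(1, 8)))
  expect_true(fit$flagged)
  # complete-case handling is reported
  fit2 <- cox_fit(data.frame(x = c(0, 1, NA, 1, 0, 1)),
                  c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 1, 0))
  expect_equal(fit2$n_dropped, 1L)
  expect_equal(fit2$n_used, 5L)
})

test_that("Cox estimates are invariant to subject order", {
  set.seed(141)
  n <- 80
  x <- rbinom(n, 1, 0.4)
  t <- rexp(n, 0.1 * exp(0.7 * x))
  e <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(data.frame(x = x), t, e)
  perm <- sample(n)
  f2 <- cox_fit(data.frame(x = x[perm]), t[perm], e[perm])
  expect_equal(f1$coefficients$log_hr, f2$coefficients$log_hr, tolerance = 1e-8)
})
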