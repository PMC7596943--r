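test_that("the problem has one unknown per arm and timepoint plus two count equalities", {
  tt <- seq(0, 50, by = 5)
  s <- seq(1, 0.5, length.out = 11)
  pts <- curve_points(tt, s, s)
  pr <- make_problem(pts, parse_pvalue("0.5"), 80, 80)
  expect_equal(pr$m, 10)
  x0 <- rep(1, 2 * pr$m)
  expect_length(kmopt:::.heq_fun(pr)(x0), 2)

  # exact P = 0.05 anchors the published quantile
  pr05 <- make_problem(pts, parse_pvalue("0.05"), 80, 80)
  expect_equal(pr05$pspec$chisq_target, 3.841, tolerance = 1e-3)

  # non-significant mode brackets the statistic
  prns <- make_problem(pts, parse_pvalue("ns"), 80, 80)
  expect_equal(prns$pspec$chisq_min, 3.9e-3, tolerance = 1e-2)
  expect_equal(prns$pspec$chisq_max, 3.841, tolerance = 1e-3)

  expect_error(make_problem(curve_points(c(0, 5), c(1, 0.9), c(1, 0.9)),
                            parse_pvalue("0.5"), 10, 10),
               "at least 3 rows")
})

test_that("the analytic chi-square gradient matches finite differences", {
  coh <- sig_cohort(seed = 8)
  oin <- oracle_curve_inputs(coh)
  pr <- make_problem(oin$points, parse_pvalue("0.1"), oin$n1_0, oin$n2_0)
  set.seed(2)
  x <- abs(rnorm(2 * pr$m, 0.8, 0.4))
  got <- kmopt:::.problem_eval(pr, x, grad = TRUE)
  h <- 1e-6
  fd <- vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- x[k] + h; xm[k] <- x[k] - h
    (kmopt:::.problem_eval(pr, xp)$chi - kmopt:::.problem_eval(pr, xm)$chi) / (2 * h)
  }, numeric(1))
  expect_equal(got$dchi, fd, tolerance = 1e-5)
})

test_that("identical curves with P = 1 give a null hazard ratio", {
  s <- c(1, 0.8, 0.6, 0.5)
  pts <- curve_points(c(0, 6, 12, 18), s, s)
  fit <- solve_from_points(pts, parse_pvalue("1"), 50, 50)
  expect_true(fit$converged)
  expect_true(fit$anchored)
  expect_equal(fit$stats$ln_hr, 0, tolerance = 1e-6)
  expect_equal(fit$stats$chi_sq, 0, tolerance = 1e-8)
})

test_that("exact-grid points with the oracle P recover the cohort statistics", {
  res <- exact_grid_fit(sig_cohort(seed = 12))
  expect_true(res$fit$converged)
  expect_true(res$fit$anchored)
  expect_lt(abs(res$fit$stats$ln_hr - res$truth$ln_hr), 0.02)
  # every converged solution satisfies the constraints tightly
  expect_lt(res$fit$constraint_residuals[["eq"]], 1e-6)
  expect_lt(res$fit$constraint_residuals[["ineq"]], 1e-6)
  # per-arm accounting: censors plus events exhaust the starting cohort
  tab <- res$fit$table
  expect_equal(sum(tab$c1) + sum(tab$e1), res$inputs$n1_0,
               tolerance = 1e-6 * res$inputs$n1_0)
  expect_equal(sum(tab$c2) + sum(tab$e2), res$inputs$n2_0,
               tolerance = 1e-6 * res$inputs$n2_0)
})

test_that("a cohort without drop-out is reconstructed with terminal-only censoring", {
  # the censor pattern matching the anchor is not unique; started from the
  # administrative pattern, the solver recovers the true terminal-only one
  coh <- generate_ipd(n1 = 50, n2 = 50, hr = 1.5, censor_rate = 0,
                      admin_time = 40, seed = 9)
  res <- exact_grid_fit(coh, config = solver_config(start = "terminal"))
  expect_true(res$fit$converged && res$fit$anchored)
  m <- length(res$fit$censors$c1)
  # all censor mass sits in the final (administrative) interval
  expect_lt(sum(res$fit$censors$c1[-m]) + sum(res$fit$censors$c2[-m]), 1e-4)
  expect_lt(abs(res$fit$stats$O1 - res$truth$O1), 0.5)
  expect_lt(abs(res$fit$stats$O2 - res$truth$O2), 0.5)
})

test_that("an exact-mode solution stays feasible under the matching bound", {
  coh <- sig_cohort(seed = 13)
  tru <- oracle_logrank(coh)
  oin <- oracle_curve_inputs(coh)
  fit <- solve_from_points(oin$points, pvalue_spec("exact", chisq = tru$chi_sq),
                           oin$n1_0, oin$n2_0)
  x <- c(fit$censors$c1, fit$censors$c2)
  # less_than with bound = the same P admits the exact solution
  pr_lt <- make_problem(oin$points,
                        pvalue_spec("less_than", value = tru$p_achieved),
                        oin$n1_0, oin$n2_0)
  expect_true(all(kmopt:::.hin_fun(pr_lt)(x) <= 1e-6))
  expect_true(all(abs(kmopt:::.heq_fun(pr_lt)(x)) <= 1e-6))
})

test_that("a grossly unattainable anchor is flagged, never silently matched", {
  # shallow curves on a small cohort cannot produce a chi-square of 500
  pts <- curve_points(c(0, 5, 10, 15), c(1, 0.95, 0.92, 0.9),
                      c(1, 0.97, 0.95, 0.94))
  fit <- solve_from_points(pts, pvalue_spec("exact", chisq = 500), 20, 20)
  expect_true(fit$converged)  # a feasible censor pattern exists
  expect_false(fit$anchored)  # but the anchor is out of reach
  expect_gt(fit$constraint_residuals[["chisq"]], 1)
})

test_that("non-exact modes land the statistic inside the published bracket", {
  coh <- sig_cohort(seed = 14, hr = 1.3)
  tru <- oracle_logrank(coh)
  oin <- oracle_curve_inputs(coh)
  fit <- solve_from_points(oin$points, pvalue_spec("nonsignificant"),
                           oin$n1_0, oin$n2_0)
  expect_true(fit$converged)
  expect_gte(fit$stats$chi_sq, p_to_chisq(0.95) - 1e-6)
  expect_lte(fit$stats$chi_sq, p_to_chisq(0.05) + 1e-6)

  bound <- degrade_pvalue(tru$p_achieved)
  fit2 <- solve_from_points(oin$points, bound, oin$n1_0, oin$n2_0)
  expect_true(fit2$converged)
  expect_gte(fit2$stats$chi_sq, bound$chisq_min - 1e-6)
})
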