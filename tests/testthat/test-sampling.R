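test_that("the 2% drop rule places points where survival falls", {
  # straight-line drop from 1.0 to 0.5: one point per 2% drop, about 25
  tt <- seq(0, 50, length.out = 101)
  s <- seq(1, 0.5, length.out = 101)
  pts <- curve_points(tt, s, s)
  rec <- recommend_times(pts)
  expect_gte(length(rec) - 2, 23)   # interior points
  expect_lte(length(rec) - 2, 27)
  expect_identical(rec[1], 0)
  expect_identical(rec[length(rec)], 50)

  # flat curve: only the endpoints
  flat <- curve_points(c(0, 10, 20), c(1, 1, 1), c(1, 1, 1))
  expect_equal(recommend_times(flat), c(0, 20))

  # on the default synthetic cohorts the rule needs 20-50 points
  for (seed in 1:3) {
    orc <- oracle_km(generate_ipd(seed = seed))
    n <- length(recommend_times(orc))
    expect_gte(n, 20)
    expect_lte(n, 50)
  }
})

test_that("uniform sampling reads step values and respects its cap", {
  coh <- sig_cohort(seed = 4)
  orc <- oracle_km(coh)

  # determinism under a seed
  a <- sample_uniform(orc, 10, seed = 7)
  b <- sample_uniform(orc, 10, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 12)  # 10 interior + baseline + final
  expect_identical(a$time[1], 0)
  expect_equal(a$time[nrow(a)], orc$t_end)

  # sampled survival values are always attained by the step function
  attained1 <- c(1, orc$arm1$surv)
  attained2 <- c(1, orc$arm2$surv)
  for (seed in 1:20) {
    p <- sample_uniform(orc, 15, seed = seed)
    expect_true(all(p$s1 %in% attained1))
    expect_true(all(p$s2 %in% attained2))
  }

  # exhaustive sampling reproduces the full truth table
  cand <- kmopt:::.candidate_times(orc)
  full <- suppressWarnings(sample_uniform(orc, length(cand) + 50, seed = 1))
  expect_warning(sample_uniform(orc, length(cand) + 50, seed = 1), "capping")
  ev <- sort(unique(c(orc$arm1$time, orc$arm2$time)))
  ev_in <- ev[ev < orc$t_end]
  expect_true(all(ev_in %in% full$time))
  expect_equal(full$s1[match(ev_in, full$time)],
               oracle_surv_at(orc, ev_in, 1L))
})

test_that("sector weights place the draws where requested", {
  coh <- sig_cohort(seed = 4)
  orc <- oracle_km(coh)
  breaks <- seq(0, orc$t_end, length.out = 4)
  plan <- sampling_plan(n_points = 30, scheme = "weighted_sectors",
                        weights = c(20, 5, 5), n_reps = 1, seed = 1)
  p <- sample_weighted(orc, plan, seed = 3)
  interior <- p$time[p$time > 0 & p$time < orc$t_end]
  sect <- findInterval(interior, breaks, rightmost.closed = TRUE)
  expect_equal(as.integer(table(factor(sect, levels = 1:3))), c(20L, 5L, 5L))

  expect_error(sampling_plan(scheme = "weighted_sectors", weights = c(10, 10)),
               "length 3")
  expect_error(sampling_plan(n_points = 30, scheme = "weighted_sectors",
                             weights = c(10, 10, 5)),
               "sum to n_points")
  degen <- structure(list(arm1 = orc$arm1, arm2 = orc$arm2, t_end = 0,
                          n1_0 = 10, n2_0 = 10), class = "km_oracle")
  expect_error(sample_weighted(degen, plan), "degenerate")
})

test_that("error metrics follow their definitions", {
  expect_equal(error_metrics(1.1, 1), list(mae = 0.1, pct_mae = 10),
               tolerance = 1e-10)
  z <- error_metrics(c(0.5, 0.7), c(0.5, 0.7))
  expect_identical(z$mae, 0)
  # invariant under a common permutation of the pairs
  e <- c(1.2, 0.8, 1.7); t <- c(1.0, 1.0, 1.5)
  expect_equal(error_metrics(e, t), error_metrics(rev(e), rev(t)))

  expect_equal(round(hr_mae_limits(1.5, 0.014), 2), c(1.48, 1.52))
  expect_equal(round(hr_mae_limits(1.5, 0.077), 2), c(1.39, 1.62))
})

test_that("the Monte-Carlo driver aggregates reproducibly", {
  coh <- generate_ipd(n1 = 60, n2 = 60, hr = 1.7, seed = 15)
  plan <- sampling_plan(n_points = 12, scheme = "uniform_random",
                        n_reps = 4, seed = 5)
  a <- run_monte_carlo(coh, plan)
  b <- run_monte_carlo(coh, plan)
  expect_equal(a, b)
  expect_equal(a$n_reps, 4)
  expect_true(a$n_failed >= 0 && a$n_failed <= 4)
  expect_gte(a$sd_lnhr, 0)
  expect_equal(a$truth_lnhr, oracle_logrank(coh)$ln_hr)
  draws <- attr(a, "draws")
  expect_equal(nrow(draws), 4)
  # summary is computed from the recorded draws
  expect_equal(a$mean_lnhr, mean(draws$ln_hr, na.rm = TRUE))
})
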