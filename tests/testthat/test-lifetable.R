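test_that("product-limit step and its inversion agree with hand arithmetic", {
  expect_identical(km_step(1, 0, 10), 1)
  expect_equal(km_step(1, 2, 10), 0.8)
  expect_equal(km_step(0.8, 4, 8), 0.4)
  expect_error(km_step(1, 1, 0), "no one at risk")
  expect_error(km_step(1, 11, 10), "e_j <= n_j")

  expect_equal(events_from_survival(10, 0.8, 1), 2)
  expect_identical(events_from_survival(50, 0.5, 0.5), 0)
  expect_equal(events_from_survival(8, 0.4, 0.8), 4)
  expect_error(events_from_survival(10, 0, 0), "already at zero")
  expect_error(events_from_survival(10, 0.9, 0.8), "cannot increase")
})

test_that("inversion round-trips the step for random feasible inputs", {
  set.seed(1)
  for (i in 1:100) {
    n <- runif(1, 1, 500)
    e <- runif(1, 0, n)
    s_prev <- runif(1, 0.05, 1)
    s_j <- km_step(s_prev, e, n)
    expect_equal(events_from_survival(n, s_j, s_prev), e, tolerance = 1e-10)
  }
})

test_that("life-table recursion reproduces chained step inversions", {
  pts <- curve_points(c(0, 6, 12), c(1, 0.8, 0.4), c(1, 0.8, 0.4))
  tab <- build_life_table(pts, censor_vector(c(0, 0), c(0, 0)), 10, 10)
  expect_equal(tab$e1, c(0, 2, 4))
  expect_equal(tab$n1, c(10, 10, 8))
  expect_equal(attr(tab, "leftover")[["arm1"]], 4)

  # censoring 2 at t1 reduces the at-risk at t2 by e1 + 2
  tabc <- build_life_table(pts, censor_vector(c(2, 0), c(0, 0)), 10, 10)
  expect_equal(tabc$n1[3], 10 - (2 + 2))
  # and scales the later events to the smaller at-risk set
  expect_equal(tabc$e1[3], 6 * (1 - 0.4 / 0.8))

  # flat curves produce no events whatever the (feasible) censoring
  flat <- curve_points(c(0, 5, 10), c(1, 1, 1), c(1, 1, 1))
  tabf <- build_life_table(flat, censor_vector(c(3, 2), c(1, 1)), 20, 20)
  expect_true(all(tabf$e1 == 0) && all(tabf$e2 == 0))
})

test_that("without censoring the events equal N times the survival drops", {
  set.seed(7)
  for (i in 1:20) {
    m <- sample(3:12, 1)
    s <- c(1, sort(runif(m, 0.1, 1), decreasing = TRUE))
    pts <- curve_points(seq(0, m), s, s)
    N <- sample(20:500, 1)
    tab <- build_life_table(pts, censor_vector(numeric(m), numeric(m)), N, N)
    expect_equal(tab$e1[-1], N * (-diff(s)), tolerance = 1e-9)
  }
})

test_that("infeasible censor patterns are signalled, or tolerated when unchecked", {
  pts <- curve_points(c(0, 6, 12), c(1, 0.8, 0.4), c(1, 0.8, 0.4))
  expect_error(build_life_table(pts, censor_vector(c(15, 0), c(0, 0)), 10, 10),
               class = "kmopt_infeasible")
  tab <- build_life_table(pts, censor_vector(c(15, 0), c(0, 0)), 10, 10,
                          check = FALSE)
  expect_lt(tab$n1[3], 0)
})

test_that("expected events follow the at-risk proportional allocation", {
  # equal arms: symmetric split
  pts <- curve_points(c(0, 5, 10), c(1, 0.9, 0.8), c(1, 0.9, 0.8))
  tab <- expected_events(build_life_table(pts, censor_vector(c(0, 0), c(0, 0)),
                                          10, 10))
  expect_equal(tab$E1[2], 1)
  expect_equal(tab$E2[2], 1)

  # 30 vs 10 at risk with 4 total events: 3 / 1
  pts2 <- curve_points(c(0, 5, 10), c(1, 1 - 2 / 30, 1 - 4 / 30),
                       c(1, 0.8, 0.6))
  tab2 <- expected_events(build_life_table(pts2, censor_vector(c(0, 0), c(0, 0)),
                                           30, 10))
  expect_equal(tab2$E1[2], 3, tolerance = 1e-9)
  expect_equal(tab2$E2[2], 1, tolerance = 1e-9)

  # no events, no expectation; and per-row conservation always
  expect_equal(tab2$E1[1], 0)
  expect_equal(tab2$E1 + tab2$E2, tab2$e1 + tab2$e2, tolerance = 1e-10)
})

test_that("summary statistics follow the O/E definitions", {
  fake <- function(e1, E1, e2, E2) {
    structure(data.frame(time = seq_along(e1) - 1,
                         n1 = 100, e1 = e1, c1 = 0, E1 = E1,
                         n2 = 100, e2 = e2, c2 = 0, E2 = E2),
              class = c("km_lifetable", "data.frame"))
  }
  s0 <- summarise_lifetable(fake(c(0, 5), c(0, 5), c(0, 5), c(0, 5)))
  expect_equal(s0$hr, 1)
  expect_equal(s0$ln_hr, 0)
  expect_equal(s0$chi_sq, 0)
  expect_equal(s0$p_achieved, 1)

  s1 <- summarise_lifetable(fake(c(0, 10), c(0, 5), c(0, 5), c(0, 10)))
  expect_equal(s1$hr, 4)
  expect_equal(s1$chi_sq, 25 / 5 + 25 / 10)

  s2 <- summarise_lifetable(fake(c(0, 8), c(0, 10), c(0, 12), c(0, 10)))
  expect_equal(s2$var_ln_hr, 0.2)
  expect_equal(summarise_lifetable(fake(c(0, 8), c(0, 10), c(0, 12), c(0, 10)),
                                   var_method = "observed")$var_ln_hr,
               1 / 8 + 1 / 12)

  # degenerate arm: signalled infinity, not a crash
  s3 <- summarise_lifetable(fake(c(0, 0), c(0, 2), c(0, 4), c(0, 2)))
  expect_identical(s3$ln_hr, -Inf)
})

test_that("the life table serialises with the documented column order", {
  pts <- small_points()
  tab <- build_life_table(pts, censor_vector(c(1, 0), c(0, 1)), 20, 20)
  f <- withr::local_tempfile(fileext = ".csv")
  write_lifetable_csv(tab, f)
  out <- utils::read.csv(f)
  expect_named(out, c("time", "n1", "e1", "c1", "E1", "n2", "e2", "c2", "E2"))
  expect_equal(nrow(out), 3)
  expect_equal(out$time, pts$time)
})
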