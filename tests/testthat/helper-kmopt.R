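# shared fixtures, all built in code

# a tiny hand-checkable cohort: arm 1 times/events chosen so the product-limit
# arithmetic can be done on paper
toy_cohort <- function() {
  data.frame(
    time = c(1, 2, 2, 4, 5, 1.5, 3, 3, 4.5, 6),
    event = c(1, 1, 0, 1, 0, 1, 1, 0, 1, 0),
    arm = rep(1:2, each = 5))
}

# default-condition synthetic cohort with a clearly significant effect
sig_cohort <- function(seed = 42, hr = 1.7) {
  generate_ipd(n1 = 100, n2 = 100, hr = hr, seed = seed)
}

# valid three-point digitized curve
small_points <- function() {
  curve_points(c(0, 6, 12), c(1, 0.9, 0.7), c(1, 0.8, 0.8))
}

# exact-grid inputs and oracle truth bundled for recovery checks
exact_grid_fit <- function(cohort, config = solver_config()) {
  tru <- oracle_logrank(cohort)
  oin <- oracle_curve_inputs(cohort)
  fit <- solve_from_points(oin$points, pvalue_spec("exact", chisq = tru$chi_sq),
                           oin$n1_0, oin$n2_0, config)
  list(fit = fit, truth = tru, inputs = oin)
}
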