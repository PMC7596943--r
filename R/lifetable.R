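#' One Kaplan-Meier product-limit step
#'
#' The product-limit recursion: survival at a timepoint is the previous
#' survival multiplied by the conditional probability of surviving the
#' interval, `S(t_j) = S(t_{j-1}) * (1 - e_j / n_j)`.
#'
#' @param s_prev survival probability at the previous timepoint, in \[0, 1\].
#' @param e_j number of events at the timepoint (real-valued, `0 <= e_j <= n_j`).
#' @param n_j number at risk just before the timepoint.
#' @return the updated survival probability, in \[0, `s_prev`\].
#' @seealso [events_from_survival()], its inverse.
#' @export
#' @examples
#' km_step(1, 2, 10)   # 0.8
#' km_step(0.8, 4, 8)  # 0.4
km_step <- function(s_prev, e_j, n_j) {
  stopifnot(is.numeric(s_prev), is.numeric(e_j), is.numeric(n_j))
  if (any(n_j == 0 & e_j > 0))
    stop("events with no one at risk (n_j = 0, e_j > 0)", call. = FALSE)
  if (any(n_j < 0) || any(e_j < 0) || any(e_j > n_j + 1e-12))
    stop("need 0 <= e_j <= n_j", call. = FALSE)
  if (any(s_prev < 0) || any(s_prev > 1))
    stop("`s_prev` must lie in [0, 1]", call. = FALSE)
  ifelse(n_j == 0, s_prev, s_prev * (1 - e_j / n_j))
}

#' Invert the product-limit step to recover event counts
#'
#' Rearranges the Kaplan-Meier step to solve for the number of events implied
#' by a drop in survival: `e_j = n_j * (1 - S(t_j) / S(t_{j-1}))`. This is the
#' inversion that lets a digitized plot, plus a censoring pattern, reproduce
#' the life table.
#'
#' @param n_j number at risk just before the timepoint (`>= 0`).
#' @param s_j survival at the timepoint.
#' @param s_prev survival at the previous timepoint (`> 0`, `>= s_j`).
#' @return the implied event count, `>= 0`; real-valued, not rounded.
#' @export
#' @examples
#' events_from_survival(10, 0.8, 1)    # 2
#' events_from_survival(50, 0.5, 0.5)  # 0: flat curve, no events
events_from_survival <- function(n_j, s_j, s_prev) {
  stopifnot(is.numeric(n_j), is.numeric(s_j), is.numeric(s_prev))
  if (any(s_prev <= 0))
    stop("`s_prev` must be > 0 (curve already at zero)", call. = FALSE)
  if (any(s_j > s_prev + 1e-12))
    stop("`s_j` exceeds `s_prev`; survival cannot increase", call. = FALSE)
  if (any(n_j < 0)) stop("`n_j` must be >= 0", call. = FALSE)
  n_j * (1 - s_j / s_prev)
}

#' Per-timepoint censor counts for both arms
#'
#' The unknowns of the reconstruction: how many subjects in each arm leave
#' observation without an event in the interval starting at each post-baseline
#' timepoint. Counts are real-valued (the optimiser works in a continuous
#' space) and non-negative; censoring at the baseline is fixed at zero.
#'
#' @param c1,c2 non-negative censor counts per post-baseline timepoint for
#'   arm 1 and arm 2; equal lengths.
#' @return an object of class `"censor_vector"`.
#' @export
censor_vector <- function(c1, c2) {
  stopifnot(is.numeric(c1), is.numeric(c2))
  if (length(c1) != length(c2))
    stop("`c1` and `c2` must have equal length", call. = FALSE)
  if (any(!is.finite(c1)) || any(!is.finite(c2)))
    stop("censor counts must be finite", call. = FALSE)
  if (any(c1 < -1e-9) || any(c2 < -1e-9))
    stop("censor counts must be non-negative", call. = FALSE)
  structure(list(c1 = pmax(c1, 0), c2 = pmax(c2, 0)), class = "censor_vector")
}

# Forward recursion for one arm. surv includes the baseline (surv[1] = 1);
# cens has one entry per post-baseline timepoint. Returns the at-risk number
# just before each post-baseline timepoint, the implied events, and the
# leftover count after the final interval (subjects never accounted for).
# No feasibility checks: negative intermediates are the optimiser's signal.
.arm_recursion <- function(surv, cens, n0) {
  m <- length(surv) - 1L
  n_at <- numeric(m)
  e <- numeric(m)
  n_cur <- n0
  for (j in seq_len(m)) {
    n_at[j] <- n_cur
    s_prev <- surv[j]
    ratio <- if (s_prev > 0) surv[j + 1L] / s_prev else 0
    e[j] <- n_cur * (1 - ratio)
    n_cur <- n_cur - e[j] - cens[j]
  }
  list(n_at = n_at, e = e, leftover = n_cur)
}

# Constant Jacobians of the arm recursion with respect to the censor vector:
# at-risk numbers and events are affine in the censors, so d n_at / d c and
# d e / d c do not depend on c. Rows 1..m of Jn are d n_at[j] / d c; row m+1
# is d leftover / d c. Je is d e[j] / d c.
.arm_jacobians <- function(surv) {
  m <- length(surv) - 1L
  Jn <- matrix(0, m + 1L, m)
  Je <- matrix(0, m, m)
  for (j in seq_len(m)) {
    s_prev <- surv[j]
    ratio <- if (s_prev > 0) surv[j + 1L] / s_prev else 0
    Je[j, ] <- (1 - ratio) * Jn[j, ]
    Jn[j + 1L, ] <- Jn[j, ] - Je[j, ]
    Jn[j + 1L, j] <- Jn[j + 1L, j] - 1
  }
  list(Jn = Jn, Je = Je)
}

#' Build the Kaplan-Meier life table implied by curve points and censors
#'
#' Runs the forward recursion independently for each arm: the at-risk number
#' carries forward minus the previous interval's events and censors, and the
#' events at each timepoint are recovered from the survival drop via
#' [events_from_survival()]. Counts are real-valued throughout.
#'
#' @param points a validated [curve_points()] object.
#' @param censors a [censor_vector()] (or list with `c1`, `c2`) of length
#'   `nrow(points) - 1`, one entry per post-baseline timepoint.
#' @param n1_0,n2_0 starting numbers at risk (positive).
#' @param check if `TRUE` (default), signal an error of class
#'   `"kmopt_infeasible"` when the censor pattern removes more subjects than
#'   exist (any intermediate at-risk count negative). The optimiser evaluates
#'   with `check = FALSE` and handles negativity through constraints.
#' @return a data frame of class `"km_lifetable"` with one row per timepoint
#'   (row 1 = baseline) and columns `time`, `n1`, `e1`, `c1`, `n2`, `e2`,
#'   `c2`; attributes `n1_0`, `n2_0` and `leftover` (per-arm subjects not
#'   accounted for by events or censoring at the end of follow-up).
#' @export
#' @examples
#' pts <- curve_points(c(0, 6, 12), c(1, 0.8, 0.4), c(1, 0.9, 0.7))
#' build_life_table(pts, censor_vector(c(0, 0), c(0, 0)), 10, 10)
build_life_table <- function(points, censors, n1_0, n2_0, check = TRUE) {
  points <- validate_points(points)
  if (!inherits(censors, "censor_vector"))
    censors <- censor_vector(censors$c1, censors$c2)
  m <- nrow(points) - 1L
  if (length(censors$c1) != m)
    stop("censor vector length ", length(censors$c1),
         " does not match the ", m, " post-baseline timepoints", call. = FALSE)
  if (!is.numeric(n1_0) || !is.numeric(n2_0) || n1_0 < 1 || n2_0 < 1)
    stop("starting numbers at risk must be >= 1", call. = FALSE)

  a1 <- .arm_recursion(points$s1, censors$c1, n1_0)
  a2 <- .arm_recursion(points$s2, censors$c2, n2_0)

  if (check) {
    tol <- 1e-9 * max(n1_0, n2_0)
    if (any(a1$n_at < -tol) || a1$leftover < -tol ||
        any(a2$n_at < -tol) || a2$leftover < -tol) {
      cnd <- structure(
        class = c("kmopt_infeasible", "error", "condition"),
        list(message = "censor pattern removes more subjects than exist (negative at-risk count)",
             call = sys.call(-1)))
      stop(cnd)
    }
  }

  tab <- data.frame(
    time = points$time,
    n1 = c(n1_0, a1$n_at), e1 = c(0, a1$e), c1 = c(0, censors$c1),
    n2 = c(n2_0, a2$n_at), e2 = c(0, a2$e), c2 = c(0, censors$c2))
  structure(tab, class = c("km_lifetable", "data.frame"),
            n1_0 = n1_0, n2_0 = n2_0,
            leftover = c(arm1 = a1$leftover, arm2 = a2$leftover))
}

#' Allocate expected events under the null of equal hazards
#'
#' The log-rank allocation: at each timepoint the total observed events are
#' split between the arms in proportion to their share of the combined
#' at-risk set, `E_ij = (e_1j + e_2j) * n_ij / (n_1j + n_2j)`. Per-timepoint
#' conservation `E_1j + E_2j = e_1j + e_2j` holds by construction.
#'
#' @param table a `"km_lifetable"` from [build_life_table()].
#' @return the table with columns `E1` and `E2` added.
#' @export
expected_events <- function(table) {
  stopifnot(inherits(table, "km_lifetable"))
  ntot <- table$n1 + table$n2
  d <- table$e1 + table$e2
  if (any(ntot <= 0 & d > 1e-12))
    stop("events at a timepoint where both arms have no one at risk",
         call. = FALSE)
  w <- ifelse(ntot > 0, table$n1 / ntot, 0)
  table$E1 <- d * w
  table$E2 <- d - table$E1
  table
}

#' Summary statistics of a reconstructed life table
#'
#' Totals the observed and expected events over the follow-up and reports the
#' meta-analysis quantities: the hazard ratio `HR = (O1/E1) / (O2/E2)` (arm 1
#' in the numerator), its natural log, the variance of ln(HR), the chi-square
#' statistic `sum_i (O_i - E_i)^2 / E_i` over the two groups, and the achieved
#' right-tail P value at 1 df.
#'
#' The variance of ln(HR) uses `1/E1 + 1/E2` by default (the expected-events
#' convention matching the O/E form of the HR); `var_method = "observed"`
#' swaps in `1/O1 + 1/O2`.
#'
#' @param table a `"km_lifetable"`; expected events are computed if absent.
#' @param var_method `"expected"` (default) or `"observed"`.
#' @return an object of class `"km_summary"`: a list with `O1`, `O2`, `E1`,
#'   `E2`, `hr`, `ln_hr`, `var_ln_hr`, `chi_sq`, `p_achieved`, `g = 2`. When
#'   an arm has no observed events the HR degenerates and `ln_hr` is returned
#'   as signed infinity rather than an error.
#' @export
summarise_lifetable <- function(table, var_method = c("expected", "observed")) {
  var_method <- match.arg(var_method)
  stopifnot(inherits(table, "km_lifetable"))
  if (is.null(table$E1)) table <- expected_events(table)
  O1 <- sum(table$e1); O2 <- sum(table$e2)
  E1 <- sum(table$E1); E2 <- sum(table$E2)
  if (E1 <= 0 || E2 <= 0) {
    hr <- NaN; ln_hr <- NaN; chi <- 0
  } else {
    hr <- (O1 / E1) / (O2 / E2)
    ln_hr <- if (O1 <= 0) -Inf else if (O2 <= 0) Inf else log(hr)
    chi <- (O1 - E1)^2 / E1 + (O2 - E2)^2 / E2
  }
  v <- switch(var_method,
    expected = if (E1 > 0 && E2 > 0) 1 / E1 + 1 / E2 else Inf,
    observed = if (O1 > 0 && O2 > 0) 1 / O1 + 1 / O2 else Inf)
  structure(list(O1 = O1, O2 = O2, E1 = E1, E2 = E2,
                 hr = hr, ln_hr = ln_hr, var_ln_hr = v,
                 chi_sq = chi, p_achieved = chisq_to_p(chi), g = 2L,
                 var_method = var_method),
            class = "km_summary")
}

#' Write a life table to CSV
#'
#' One row per timepoint (row 1 = baseline) with columns
#' `time, n1, e1, c1, E1, n2, e2, c2, E2`.
#'
#' @param table a `"km_lifetable"`.
#' @param path output file path.
#' @param digits rounding for display; `NULL` (default) writes full precision.
#' @return the path, invisibly.
#' @export
write_lifetable_csv <- function(table, path, digits = NULL) {
  stopifnot(inherits(table, "km_lifetable"))
  if (is.null(table$E1)) table <- expected_events(table)
  out <- as.data.frame(table)[c("time", "n1", "e1", "c1", "E1",
                                "n2", "e2", "c2", "E2")]
  if (!is.null(digits)) out[-1] <- lapply(out[-1], round, digits = digits)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.km_summary <- function(x, ...) {
  cat("Two-arm life-table summary\n")
  cat(sprintf("  O1 = %.4f  E1 = %.4f | O2 = %.4f  E2 = %.4f\n",
              x$O1, x$E1, x$O2, x$E2))
  cat(sprintf("  HR (arm1 vs arm2) = %.4f   ln(HR) = %.4f   var ln(HR) = %.5f\n",
              x$hr, x$ln_hr, x$var_ln_hr))
  cat(sprintf("  chi-square (1 df) = %.4f   P = %.4g\n", x$chi_sq, x$p_achieved))
  invisible(x)
}
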