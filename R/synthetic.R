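#' Generate a synthetic two-arm survival cohort
#'
#' Simulates individual-patient data under proportional hazards: event times
#' follow a Weibull model `S_i(t) = exp(-rate_i * t^shape)` with
#' `rate_1 = baseline_rate * hr` and `rate_2 = baseline_rate` (so `hr` is the
#' arm-1 versus arm-2 hazard ratio), `shape = 1` (the default) giving
#' exponential times. Subjects are censored by an independent exponential
#' drop-out process and administratively at the study end.
#'
#' Defaults describe a typical oncology-scale cohort: 100 subjects per arm, a
#' baseline hazard of 0.02 events per month (median survival about 35
#' months), drop-out at 0.01 per month and 60 months of follow-up — curves
#' that end around a survival of 0.3 with roughly a third of subjects
#' censored.
#'
#' @param n1,n2 subjects per arm.
#' @param hr true arm-1 vs arm-2 hazard ratio (> 0).
#' @param baseline_rate arm-2 event hazard, events per time unit (> 0).
#' @param censor_rate drop-out hazard per time unit (`0` disables drop-out).
#' @param admin_time administrative censoring time (`Inf` disables it).
#' @param seed optional integer seed for reproducibility.
#' @param shape Weibull shape; `1` (default) keeps times exponential, other
#'   values stress the proportional-hazards assumption.
#' @return a data frame of class `"ipd_cohort"` with columns `time`, `event`
#'   (1 = event, 0 = censored), `arm` (1 or 2), and the generating parameters
#'   stored in `attr(, "params")`.
#' @export
#' @examples
#' coh <- generate_ipd(n1 = 50, n2 = 50, hr = 2, seed = 42)
#' table(coh$arm, coh$event)
generate_ipd <- function(n1 = 100L, n2 = 100L, hr = 1, baseline_rate = 0.02,
                         censor_rate = 0.01, admin_time = 60, seed = NULL,
                         shape = 1) {
  stopifnot(n1 >= 1, n2 >= 1, hr > 0, baseline_rate > 0, censor_rate >= 0,
            admin_time > 0, shape > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  arm <- rep(1:2, c(n1, n2))
  rate <- ifelse(arm == 1L, baseline_rate * hr, baseline_rate)
  t_event <- (stats::rexp(n) / rate)^(1 / shape)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, admin_time)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  out <- data.frame(time = time, event = event, arm = arm)
  structure(out, class = c("ipd_cohort", "data.frame"),
            params = list(n1 = n1, n2 = n2, hr = hr,
                          baseline_rate = baseline_rate,
                          censor_rate = censor_rate,
                          admin_time = admin_time, seed = seed,
                          shape = shape))
}

# per-arm product-limit pieces: distinct event times, at-risk and event
# counts, survival. Censoring at an event time keeps the subject at risk for
# the events at that time (events-before-censoring convention).
.arm_km <- function(time, event) {
  te <- sort(unique(time[event == 1L]))
  if (!length(te))
    return(list(time = numeric(0), n_risk = numeric(0),
                n_event = numeric(0), surv = numeric(0)))
  n_risk <- vapply(te, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(te, function(t) sum(time == t & event == 1L), numeric(1))
  list(time = te, n_risk = n_risk, n_event = n_event,
       surv = cumprod(1 - n_event / n_risk))
}

#' Exact Kaplan-Meier step functions of a cohort
#'
#' The product-limit estimate computed directly from the individual-patient
#' data, per arm: distinct event times, at-risk and event counts, and the
#' survival step values. These dense truth curves are what the point-sampling
#' experiments read from.
#'
#' @param cohort an `"ipd_cohort"` (any data frame with `time`, `event`,
#'   `arm`).
#' @return a list of class `"km_oracle"` with elements `arm1`, `arm2` (each
#'   `time`, `n_risk`, `n_event`, `surv`), `obs_times` (distinct observed
#'   times of either arm, event or censoring — the rows of the stored KM
#'   table, hence the candidate times for point sampling), `t_end` (latest
#'   observed time in either arm), `n1_0`, `n2_0`.
#' @export
oracle_km <- function(cohort) {
  stopifnot(all(c("time", "event", "arm") %in% names(cohort)))
  a1 <- cohort$arm == 1L; a2 <- cohort$arm == 2L
  structure(list(arm1 = .arm_km(cohort$time[a1], cohort$event[a1]),
                 arm2 = .arm_km(cohort$time[a2], cohort$event[a2]),
                 obs_times = sort(unique(cohort$time)),
                 t_end = max(cohort$time),
                 n1_0 = sum(a1), n2_0 = sum(a2)),
            class = "km_oracle")
}

#' Read a survival probability off an oracle curve
#'
#' Right-continuous step-function evaluation: the survival at the latest
#' event time at or before `t` (1 before the first event) — exactly what
#' reading a KM plot at a vertical line does.
#'
#' @param oracle a `"km_oracle"`.
#' @param t time(s) to evaluate at.
#' @param arm 1 or 2.
#' @return survival probabilities at `t`.
#' @export
oracle_surv_at <- function(oracle, t, arm) {
  a <- if (arm == 1L) oracle$arm1 else oracle$arm2
  if (!length(a$time)) return(rep(1, length(t)))
  idx <- findInterval(t, a$time)
  c(1, a$surv)[idx + 1L]
}

#' Exact log-rank ground truth of a cohort
#'
#' Computes the observed and expected event totals per arm over the union of
#' distinct event times directly from the individual-patient data, then the
#' same summary statistics the reconstruction reports: the O/E hazard ratio,
#' ln(HR), var ln(HR), the two-group chi-square `sum (O_i - E_i)^2 / E_i` and
#' its right-tail P value. This is the anchor fed to the optimiser in
#' recovery experiments, and the truth the estimates are scored against.
#'
#' @param cohort an `"ipd_cohort"`.
#' @param var_method variance convention, see [summarise_lifetable()].
#' @return a `"km_summary"` list, as from [summarise_lifetable()].
#' @export
oracle_logrank <- function(cohort, var_method = c("expected", "observed")) {
  var_method <- match.arg(var_method)
  stopifnot(all(c("time", "event", "arm") %in% names(cohort)))
  te <- sort(unique(cohort$time[cohort$event == 1L]))
  if (!length(te)) stop("cohort has no events", call. = FALSE)
  t1 <- cohort$time[cohort$arm == 1L]; v1 <- cohort$event[cohort$arm == 1L]
  t2 <- cohort$time[cohort$arm == 2L]; v2 <- cohort$event[cohort$arm == 2L]
  n1 <- vapply(te, function(t) sum(t1 >= t), numeric(1))
  n2 <- vapply(te, function(t) sum(t2 >= t), numeric(1))
  e1 <- vapply(te, function(t) sum(t1 == t & v1 == 1L), numeric(1))
  e2 <- vapply(te, function(t) sum(t2 == t & v2 == 1L), numeric(1))
  d <- e1 + e2
  E1 <- d * n1 / (n1 + n2)
  O1 <- sum(e1); O2 <- sum(e2)
  E1t <- sum(E1); E2t <- O1 + O2 - E1t
  hr <- (O1 / E1t) / (O2 / E2t)
  chi <- (O1 - E1t)^2 / E1t + (O2 - E2t)^2 / E2t
  v <- switch(var_method,
              expected = 1 / E1t + 1 / E2t,
              observed = 1 / O1 + 1 / O2)
  structure(list(O1 = O1, O2 = O2, E1 = E1t, E2 = E2t,
                 hr = hr, ln_hr = log(hr), var_ln_hr = v,
                 chi_sq = chi, p_achieved = chisq_to_p(chi), g = 2L,
                 var_method = var_method),
            class = "km_summary")
}

#' Exact life-table inputs for a cohort
#'
#' Builds the [curve_points()] and [censor_vector()] that reproduce a
#' cohort's life table exactly: one timepoint per distinct event time (of
#' either arm) with the true product-limit survival values, censor counts
#' allocated to the interval beginning at each timepoint, and — when any
#' subject is censored before the first event — one auxiliary flat timepoint
#' that carries that early censoring (a censoring-only interval). Feeding
#' these into [build_life_table()] and [summarise_lifetable()] reproduces
#' [oracle_logrank()] to numerical precision.
#'
#' @param cohort an `"ipd_cohort"`.
#' @return a list with `points`, `censors`, `n1_0`, `n2_0`.
#' @export
oracle_curve_inputs <- function(cohort) {
  stopifnot(all(c("time", "event", "arm") %in% names(cohort)))
  te <- sort(unique(cohort$time[cohort$event == 1L]))
  if (length(te) < 2L) stop("need at least two distinct event times", call. = FALSE)
  grid <- te
  cmin <- suppressWarnings(min(cohort$time[cohort$event == 0L]))
  if (is.finite(cmin) && cmin < te[1]) grid <- c(te[1] / 2, grid)
  ok <- oracle_km(cohort)
  s1 <- oracle_surv_at(ok, grid, 1L)
  s2 <- oracle_surv_at(ok, grid, 2L)
  pts <- curve_points(c(0, grid), c(1, s1), c(1, s2))
  # censor counts per interval: bucket k spans up to grid_{k+1}, the first
  # bucket reaching back to 0 (covers the auxiliary early-censoring point),
  # the last open-ended
  cuts <- c(0, grid[-1L], Inf)
  cens_counts <- function(arm) {
    ct <- cohort$time[cohort$arm == arm & cohort$event == 0L]
    vapply(seq_along(grid),
           function(k) sum(ct >= cuts[k] & ct < cuts[k + 1L]), numeric(1))
  }
  list(points = pts, censors = censor_vector(cens_counts(1L), cens_counts(2L)),
       n1_0 = ok$n1_0, n2_0 = ok$n2_0)
}

#' Write a cohort to CSV with its ground truth alongside
#'
#' @param cohort an `"ipd_cohort"`.
#' @param path output CSV path (`time,event,arm`).
#' @param truth_path optional path for a JSON file with the generating
#'   parameters and the exact log-rank truth ([oracle_logrank()]).
#' @return `path`, invisibly.
#' @export
write_ipd_csv <- function(cohort, path, truth_path = NULL) {
  utils::write.csv(as.data.frame(cohort)[c("time", "event", "arm")], path,
                   row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- oracle_logrank(cohort)
    jsonlite::write_json(
      list(params = attr(cohort, "params"),
           truth = truth[c("O1", "O2", "E1", "E2", "hr", "ln_hr",
                           "var_ln_hr", "chi_sq", "p_achieved")]),
      truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
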