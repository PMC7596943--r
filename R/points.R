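#' Digitized survival-curve points for two arms
#'
#' The raw material of the reconstruction: survival probabilities read off a
#' published Kaplan-Meier plot at a common set of times for both arms. The
#' baseline row (t = 0, S = 1 for each arm) is mandatory; times must strictly
#' increase and each arm's survival must be non-increasing. Flat segments are
#' meaningful (censoring-only intervals). A survival probability of exactly 0
#' is permitted only at the final timepoint.
#'
#' @param time study times, starting at 0, strictly increasing.
#' @param s1,s2 survival probabilities for arm 1 and arm 2 at `time`.
#' @return a data frame of class `"curve_points"` with columns `time`, `s1`,
#'   `s2`.
#' @seealso [validate_points()], [read_points_csv()], [align_final_timepoint()]
#' @export
#' @examples
#' curve_points(c(0, 6, 12), c(1, 0.9, 0.7), c(1, 0.8, 0.8))
curve_points <- function(time, s1, s2) {
  validate_points(data.frame(time = time, s1 = s1, s2 = s2))
}

#' Validate digitized curve points
#'
#' Enforces the input rules before any optimisation: numeric finite values, at
#' least three rows including the baseline, `time[1] == 0` with survival 1 in
#' both arms, strictly increasing times (duplicated times rejected), survival
#' non-increasing within each arm and confined to \[0, 1\], and zero survival
#' only at the final row. Rejections name the offending row and rule.
#' Idempotent: validated output re-validates unchanged.
#'
#' @param x a data frame (or list) with columns `time`, `s1`, `s2`; the
#'   aliases `t`, `y1`, `y2` are accepted.
#' @return the normalised `"curve_points"` data frame.
#' @export
validate_points <- function(x) {
  x <- as.data.frame(x)
  nm <- tolower(names(x))
  nm[nm == "t"] <- "time"; nm[nm == "y1"] <- "s1"; nm[nm == "y2"] <- "s2"
  names(x) <- nm
  need <- c("time", "s1", "s2")
  if (!all(need %in% nm))
    stop("points need columns time, s1, s2 (or t, y1, y2); got: ",
         paste(names(x), collapse = ", "), call. = FALSE)
  x <- x[need]
  for (col in need) {
    v <- x[[col]]
    if (!is.numeric(v))
      stop("column ", sQuote(col), " is not numeric", call. = FALSE)
    if (any(!is.finite(v)))
      stop("column ", sQuote(col), " has non-finite values at row(s) ",
           paste(which(!is.finite(v)), collapse = ", "),
           "; if one arm ends earlier, run align_final_timepoint() first",
           call. = FALSE)
  }
  n <- nrow(x)
  if (n < 3L)
    stop("need at least 3 rows (baseline plus two timepoints); got ", n,
         call. = FALSE)
  if (x$time[1] != 0)
    stop("row 1: the baseline time must be 0 (got ", x$time[1], ")",
         call. = FALSE)
  dup <- which(diff(x$time) == 0)
  if (length(dup))
    stop("row ", dup[1] + 1L, ": duplicated time value ", x$time[dup[1] + 1L],
         "; times must strictly increase", call. = FALSE)
  bad <- which(diff(x$time) < 0)
  if (length(bad))
    stop("row ", bad[1] + 1L, ": time decreases; times must strictly increase",
         call. = FALSE)
  for (arm in c("s1", "s2")) {
    v <- x[[arm]]
    if (v[1] != 1)
      stop("row 1: baseline survival in ", arm, " must be 1 (got ", v[1], ")",
           call. = FALSE)
    if (any(v < 0 | v > 1))
      stop("row ", which(v < 0 | v > 1)[1], ": ", arm,
           " outside [0, 1]", call. = FALSE)
    up <- which(diff(v) > 0)
    if (length(up))
      stop("row ", up[1] + 1L, ": ", arm,
           " increases from ", v[up[1]], " to ", v[up[1] + 1L],
           "; survival must be non-increasing", call. = FALSE)
    zero <- which(v == 0)
    if (length(zero) && zero[1] < n)
      stop("row ", zero[1], ": ", arm,
           " reaches 0 before the final timepoint; zero survival is only ",
           "allowed at the last row", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("curve_points", "data.frame")
  x
}

#' Read digitized points from a CSV file
#'
#' Comma-separated with a header naming the three columns `time,s1,s2` (or
#' `t,y1,y2`), dot decimal separator. The file is validated after an
#' [align_final_timepoint()] pass, so one arm's trailing blanks (an arm whose
#' curve ends earlier) are carried forward rather than rejected.
#'
#' @param path path to the CSV file.
#' @return a validated `"curve_points"` data frame.
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, strip.white = TRUE)
  validate_points(align_final_timepoint(raw))
}

#' Carry a shorter arm forward to the common final timepoint
#'
#' When one arm's curve ends before the other's, the published plot still
#' shows the later time for the longer arm; the shorter arm's last survival
#' value is carried forward to that common final time. In the three-column
#' format this shows up as trailing missing values for the shorter arm, which
#' this function fills with the arm's last observed survival. Already-aligned
#' input is returned unchanged.
#'
#' @param x a data frame with columns `time`, `s1`, `s2` (aliases accepted);
#'   trailing `NA`s allowed in `s1` or `s2`.
#' @return the aligned data frame (not yet validated).
#' @export
align_final_timepoint <- function(x) {
  x <- as.data.frame(x)
  nm <- tolower(names(x))
  nm[nm == "t"] <- "time"; nm[nm == "y1"] <- "s1"; nm[nm == "y2"] <- "s2"
  names(x) <- nm
  for (arm in intersect(c("s1", "s2"), nm)) {
    v <- x[[arm]]
    na <- is.na(v)
    if (!any(na)) next
    last_obs <- max(which(!na))
    if (any(na[seq_len(last_obs)]))
      stop("interior missing value in ", arm, " at row ",
           which(na[seq_len(last_obs)])[1],
           "; only trailing gaps can be aligned", call. = FALSE)
    v[(last_obs + 1L):length(v)] <- v[last_obs]
    x[[arm]] <- v
  }
  x
}

#' @export
print.curve_points <- function(x, ...) {
  cat(sprintf("Digitized KM curve points: %d timepoints over [0, %g]\n",
              nrow(x), max(x$time)))
  print.data.frame(x, ...)
  invisible(x)
}
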