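#' Convert a right-tailed P value to a 1-df chi-square statistic
#'
#' Inverts the survival function of the chi-square distribution with one
#' degree of freedom, the reference distribution of the two-group log-rank
#' statistic. This is the anchor that links a published P value to the
#' reconstruction: `p_to_chisq(0.05)` is 3.841, `p_to_chisq(0.95)` is 0.0039.
#'
#' @param p right-tail probability, in (0, 1]. Vectorised.
#' @return the chi-square value(s) whose right-tail probability is `p`;
#'   strictly decreasing in `p`, with `p_to_chisq(1) == 0`.
#' @seealso [chisq_to_p()] for the forward direction.
#' @export
#' @examples
#' p_to_chisq(0.05)
#' p_to_chisq(c(1, 0.95, 0.05))
p_to_chisq <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || any(!is.finite(p)))
    stop("`p` must be a finite numeric vector", call. = FALSE)
  if (any(p <= 0) || any(p > 1))
    stop("`p` must lie in (0, 1]", call. = FALSE)
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Right-tail P value of a 1-df chi-square statistic
#'
#' @param chisq non-negative chi-square value(s).
#' @return right-tail probability under 1 df.
#' @export
chisq_to_p <- function(chisq) {
  if (!is.numeric(chisq) || any(!is.finite(chisq)) || any(chisq < 0))
    stop("`chisq` must be non-negative and finite", call. = FALSE)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Specify the published P value that anchors the optimisation
#'
#' A published P value constrains the log-rank chi-square of the reconstructed
#' life table. Three reporting styles are supported:
#' \describe{
#'   \item{`exact`}{"P = 0.03": the chi-square must equal `p_to_chisq(0.03)`
#'     (an equality constraint).}
#'   \item{`less_than`}{"P < 0.01": the chi-square must be at least
#'     `p_to_chisq(0.01)` (smaller P means larger statistic).}
#'   \item{`nonsignificant`}{"ns" or "P > 0.05": the chi-square is bracketed
#'     between `p_to_chisq(0.95)` = 0.0039 and `p_to_chisq(0.05)` = 3.841.}
#' }
#'
#' @param mode one of `"exact"`, `"less_than"`, `"nonsignificant"`.
#' @param value the published P value (required for `exact` and `less_than`).
#' @param chisq optionally, the chi-square statistic itself (some papers print
#'   it instead of P); only meaningful with `mode = "exact"`.
#' @return an object of class `"pvalue_spec"` with elements `mode`, `value`,
#'   `chisq_target` (exact mode) and `chisq_min`/`chisq_max` (bounds).
#' @seealso [parse_pvalue()] to build one from the published text.
#' @export
pvalue_spec <- function(mode = c("exact", "less_than", "nonsignificant"),
                        value = NULL, chisq = NULL) {
  mode <- match.arg(mode)
  out <- list(mode = mode, value = value,
              chisq_target = NA_real_, chisq_min = 0, chisq_max = Inf)
  if (mode == "exact") {
    if (!is.null(chisq)) {
      if (!is.numeric(chisq) || length(chisq) != 1L || chisq < 0 || !is.finite(chisq))
        stop("`chisq` must be a single non-negative number", call. = FALSE)
      out$chisq_target <- as.numeric(chisq)
      out$value <- chisq_to_p(chisq)
    } else {
      if (is.null(value)) stop("exact mode requires `value`", call. = FALSE)
      out$chisq_target <- p_to_chisq(value)
    }
  } else if (mode == "less_than") {
    if (is.null(value)) stop("less_than mode requires `value`", call. = FALSE)
    out$chisq_min <- p_to_chisq(value)
  } else { # nonsignificant: 0.05 < p <= 0.95
    out$chisq_min <- p_to_chisq(0.95)
    out$chisq_max <- p_to_chisq(0.05)
  }
  class(out) <- "pvalue_spec"
  out
}

#' Parse a published P value string
#'
#' Accepts the forms in which survival papers report significance:
#' an exact value (`"0.03"`), a bound (`"<0.01"`, `"< 0.001"`), a
#' non-significance marker (`"ns"`, `"n.s."`, `">0.05"`), or the chi-square
#' statistic directly via a `"chisq:"` prefix (`"chisq:5.991"`).
#'
#' @param text the published P value, as a single string.
#' @return a [pvalue_spec()] object.
#' @export
#' @examples
#' parse_pvalue("0.03")
#' parse_pvalue("<0.05")
#' parse_pvalue("ns")
parse_pvalue <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("`text` must be a single non-empty string", call. = FALSE)
  s <- tolower(gsub("[[:space:]]", "", text))
  s <- sub("^p=", "", s)
  if (grepl("^chisq:", s)) {
    x <- suppressWarnings(as.numeric(sub("^chisq:", "", s)))
    if (is.na(x) || x < 0)
      stop("unparseable chi-square value in ", sQuote(text), call. = FALSE)
    return(pvalue_spec("exact", chisq = x))
  }
  if (s %in% c("ns", "n.s.", "n.s", "nonsignificant", "non-significant"))
    return(pvalue_spec("nonsignificant"))
  if (grepl("^<", s)) {
    x <- suppressWarnings(as.numeric(sub("^<", "", s)))
    if (is.na(x) || x <= 0 || x > 1)
      stop("P value bound in ", sQuote(text), " must lie in (0, 1]", call. = FALSE)
    return(pvalue_spec("less_than", value = x))
  }
  if (grepl("^>", s)) {
    x <- suppressWarnings(as.numeric(sub("^>", "", s)))
    if (is.na(x) || x <= 0 || x >= 1)
      stop("P value bound in ", sQuote(text), " must lie in (0, 1)", call. = FALSE)
    return(pvalue_spec("nonsignificant"))
  }
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x) || x <= 0 || x > 1)
    stop("unparseable P value ", sQuote(text), "; expected e.g. \"0.03\", \"<0.01\", \"ns\"",
         call. = FALSE)
  pvalue_spec("exact", value = x)
}

#' Degrade an exact P value to a non-exact reporting scale
#'
#' Emulates how studies quote non-exact P values: the bound one "scale" above
#' the exact value on the conventional ladder 0.0001, 0.001, 0.005, 0.01, 0.05
#' (an exact P of 0.005 is reported as "< 0.01"; 0.01 as "< 0.05"). Values
#' above 0.05 become a non-significant bracket. Used to stress-test the
#' optimiser under the information loss of non-exact reporting.
#'
#' @param p the exact P value, in (0, 1].
#' @return a [pvalue_spec()] in `less_than` or `nonsignificant` mode.
#' @export
degrade_pvalue <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("`p` must be a single value in (0, 1]", call. = FALSE)
  ladder <- c(1e-4, 1e-3, 5e-3, 1e-2, 5e-2)
  if (p > max(ladder)) return(pvalue_spec("nonsignificant"))
  above <- ladder[ladder > p]
  bound <- if (length(above)) min(above) else min(ladder)
  pvalue_spec("less_than", value = bound)
}

#' @export
print.pvalue_spec <- function(x, ...) {
  switch(x$mode,
    exact = cat(sprintf("P value spec: exact P = %g (chi-square target %.4g)\n",
                        x$value, x$chisq_target)),
    less_than = cat(sprintf("P value spec: P < %g (chi-square >= %.4g)\n",
                            x$value, x$chisq_min)),
    nonsignificant = cat(sprintf(
      "P value spec: non-significant, 0.05 < P <= 0.95 (chi-square in [%.4g, %.4g])\n",
      x$chisq_min, x$chisq_max)))
  invisible(x)
}
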