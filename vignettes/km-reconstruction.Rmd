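---
title: "Reconstructing hazard ratios from Kaplan-Meier plots anchored on the published P value"
author: "kmopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing hazard ratios from Kaplan-Meier plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmopt)
```

## The problem and the model

A two-arm Kaplan-Meier plot encodes almost everything a meta-analyst needs:
the product-limit recursion
$S(t_j) = S(t_{j-1})\,(1 - e_j/n_j)$
links the plotted survival probabilities to the per-interval event counts
$e_j$ and at-risk numbers $n_j$. What the plot does not show is censoring.
Writing the at-risk recursion as
$n_j = n_{j-1} - (c_{j-1} + e_{j-1})$ and inverting the product-limit step,
$e_j = n_j\,(1 - S(t_j)/S(t_{j-1}))$,
the whole life table of each arm becomes a deterministic function of the
digitized curve, the starting number at risk $N_0$, and the unknown censor
counts $c_j \ge 0$.

A published log-rank (or Cox score) P value supplies one more, powerful
constraint. With expected events allocated under the null in proportion to
the at-risk split, $E_{ij} = (e_{1j}+e_{2j})\,n_{ij}/(n_{1j}+n_{2j})$, the
two-group statistic
$X^2 = \sum_i (O_i - E_i)^2 / E_i$
is $\chi^2_1$-distributed, so a published $P$ fixes
$X^2 = Q(P) \equiv$ `p_to_chisq(P)`. `kmopt` therefore solves, by
sequential quadratic programming (SLSQP, via `nloptr`):

* decision vector: the censor counts of both arms at every post-baseline
  timepoint ($2m$ coordinates; baseline censoring fixed at 0);
* bounds: $c \ge 0$ (no upper bound);
* equalities: per-arm accounting, $\sum_j c_{ij} + \sum_j e_{ij} = N_{i,0}$
  (equivalently, no subject left unaccounted at the end of follow-up);
* inequalities: every intermediate at-risk count non-negative;
* the anchor: for an exact P the objective $(X^2(c) - Q(P))^2$ is driven to
  zero; for "$P < \alpha$" the constraint $X^2 \ge Q(\alpha)$ applies (a
  smaller P means a larger statistic), and for "not significant" the
  bracket $Q(0.95) = 0.0039 \le X^2 \le Q(0.05) = 3.841$; in these
  non-exact modes the objective is a smoothness regulariser (the sum of
  squared censor increments), selecting the smoothest censoring pattern in
  the feasible set, which the anchoring information leaves unidentified.

From the solved table the package reports the meta-analysis pair
$\ln\mathrm{HR}$, with $\mathrm{HR} = (O_1/E_1)/(O_2/E_2)$ (arm 1 in the
numerator), and $\operatorname{var}\ln\mathrm{HR} = 1/E_1 + 1/E_2$ by
default — the expected-events convention consistent with the O/E form of
the estimator; `var_method = "observed"` substitutes $1/O_1 + 1/O_2$.

Counts are real-valued throughout: the optimiser needs a smooth space, and
nothing in the arithmetic requires integers. Rounding is offered only for
display.

### Assumptions and scope

The anchoring P value comes from tests built on proportional hazards, so
the method is expected to work best when PH holds; it does not test PH.
It reports summary statistics only — it does not reconstruct
individual-patient data. And it requires the starting numbers at risk of
both arms (usually the enrolment numbers in the text), though not the
number-at-risk row under the plot.

## Numerical design

**Gradients.** The at-risk and event counts are affine functions of the
censor vector, so the Jacobians of the accounting and at-risk constraints
are constant and computed once per problem; the chi-square gradient is
assembled analytically by the chain rule (validated against finite
differences to ~1e-9 in the test suite). This keeps a 50-timepoint solve in
the tens of milliseconds.

**Starts.** SLSQP is local, and the constraint set — one statistic plus two
totals for $2m$ unknowns — is under-determined, so the starting point acts
as the prior over censor patterns. The default first start spreads each
arm's residual mass $N_0 S(t_m)$ evenly over the timepoints (the classic
constant-censoring assumption); fallbacks are the terminal pattern (all
residual mass censored administratively at the end), all-zeros, and seeded
random simplex draws, up to `n_multistart = 8`. The uniform-first policy
measurably outperforms terminal-first on cohorts with steady drop-out
(median ln(HR) error 0.015 vs 0.025 in our calibration runs) and is kept as
the default; `solver_config(start = "terminal")` is available when
censoring is known to be administrative, in which case the solver recovers
a terminal-only pattern exactly on drop-out-free data.

**Non-identifiability.** Because many censor patterns reproduce the same
anchor, per-arm event totals $O_i$ are *not* identified — two exact-anchor
solutions can differ by dozens of events — while $\ln\mathrm{HR}$, a ratio
of O/E ratios, is empirically stable across that manifold. Users should
treat the reconstructed life table as *a* table consistent with the plot
and the P value, not *the* table.

**Tolerances.** Feasibility (count equalities, scaled by $N_0$; at-risk
non-negativity) is enforced at `tol_constraint = 1e-6`. The chi-square
anchor is treated differently: a digitized grid coarser than the true event
times aggregates events, so the published statistic is often approachable
but not exactly attainable on that grid, and a published P value itself
carries only ~2 significant figures ($P = 0.05$ vs $0.051$ already moves
the statistic by 0.03). A solve is `converged` when feasible, and
additionally `anchored` when $|X^2 - Q(P)| \le 0.05\,\max(1, Q(P))$; the
achieved gap is always reported. The command-line tool fails loudly (exit
3) when the anchor is out of reach — for an end user that means the inputs
are inconsistent — while the Monte-Carlo driver keeps feasible best-effort
estimates, which is what the point-count experiments are about at very
sparse grids. Iteration cap 1000, objective stopping tolerance 1e-10, all
configurable via `solver_config()`.

**Degenerate inputs.** Zero survival is allowed only at the final
timepoint and is absorbing (the step consumes everyone at risk). Flat
segments are legitimate censoring-only intervals. Duplicate times, rising
survival, a missing baseline row, or interior missing values are rejected
with the offending row named; a shorter arm is first carried forward to the
common final time by `align_final_timepoint()`, the convention for plots
whose arms end at different times.

## The synthetic-data generator and what it emulates

`generate_ipd()` simulates per-patient records under proportional hazards:
event times with survival $\exp(-r_i t^{k})$, where $r_1 = r\,\mathrm{HR}$,
$r_2 = r$, shape $k = 1$ by default (exponential; $k \ne 1$ available for
PH-stress experiments), independent exponential drop-out, and
administrative censoring at study end. The defaults — 100 patients per arm,
$r = 0.02$/month, drop-out 0.01/month, 60 months of follow-up — emulate a
typical oncology-scale study whose curves end near $S = 0.3$ with roughly a
third of subjects censored; on such curves the 2%-drop placement rule asks
for 20–50 points, the regime the rule was designed for.

`oracle_km()` and `oracle_logrank()` compute the exact product-limit
curves and the log-rank O/E table directly from the simulated patients
(cross-checked against the `survival` package to 1e-8 in the tests), and
`oracle_curve_inputs()` emits the exact grid — one timepoint per distinct
event time, true interval censor counts, plus one auxiliary flat timepoint
when anyone is censored before the first event — on which the life-table
pipeline reproduces the oracle to machine precision.

What the generator does **not** emulate: digitization error (points are
read exactly off the step function), non-PH hazards beyond the Weibull
shape, informative censoring, and ties (continuous times make them
measure-zero). Passing tests therefore demonstrate the method's arithmetic
and optimisation behaviour under clean inputs, not robustness to
plot-reading error.

## The simulation experiments

`run_monte_carlo()` repeats: draw a point subset from the truth curves,
anchor the P value, solve, record $\ln\mathrm{HR}$ and its variance.
Candidate times are every distinct observed time — event or censoring, the
rows of the stored KM table. Survival is read as the right-continuous step
value at the drawn time, which is what reading a plot at a vertical line
does. Point counts run 5–30 at 25 repetitions per condition in the shipped
tests and acceptance script (the protocol scales to 100 repetitions and 50
points unchanged; the smaller sizes keep a full run on one CPU in minutes
and are the package's chosen default problem size). Non-exact anchoring
degrades the exact P one "scale" up the conventional reporting ladder
(0.0001, 0.001, 0.005, 0.01, 0.05; above that, the non-significant
bracket), mirroring how papers actually round.

Findings reproduced by the shipped experiments, at a clearly significant
effect (HR 1.7, default cohort):

* dispersion of $\ln\mathrm{HR}$ across point draws falls as the point
  count grows from 5 to 30 and plateaus around 20–30 points;
* a non-exact anchor does not recover accuracy with more points, and at
  matched settings its estimates are more dispersed and more biased than
  exact-anchor estimates;
* on a curve whose events concentrate in the first half of follow-up,
  back-loading 20 of 30 points onto the flat final sector degrades accuracy
  most, front-loading helps slightly, and mid-heavy or uniform placement
  sits in between — hence the practical rule: place a point wherever either
  curve has dropped about 2% (`recommend_times()`).

Both comparative findings are regime-dependent, not universal: on cohorts
where the exact anchor is itself barely attainable (borderline
significance, sparse grids) the exact-mode dispersion can exceed the
non-exact mode's, and on curves with essentially all events in the first
sector the mid- and late-weighted schemes become indistinguishable. The
acceptance script reports the measured values for whatever seed it is
given rather than asserting the orderings unconditionally.

## Choices made where the design was open

* **Expected events**: the standard conditional log-rank allocation — it is
  what the two-group chi-square presumes.
* **Variance of ln(HR)**: $1/E_1 + 1/E_2$, switchable to the observed-count
  form; neither is privileged by the anchoring information.
* **Exact mode as a penalised objective**: minimising $(X^2 - Q(P))^2$
  under the count constraints is algebraically equivalent to the equality-
  constrained statement but gives the SQP solver a smooth merit direction,
  and degrades gracefully to the closest attainable statistic on coarse
  grids.
* **Censoring at the baseline** is fixed at zero: the baseline row is a
  definition ($t_0 = 0$, $S = 1$), not an observation interval.
* **Arm orientation**: arm 1 (first survival column) is the HR numerator,
  documented on the CLI.
* **P values printed as statistics** are accepted via a `"chisq:"` prefix,
  since some papers print the chi-square instead of P.

## Known limitations

Accuracy is bounded by the quality of digitization, which the package does
not perform; the anchoring P value must be log-rank/Cox-based and two-arm
($g = 2$ throughout); non-exact anchors are supported but not recommended
when an exact P is available; and the reconstructed censor pattern (and
with it the per-arm event totals) is one representative of a feasible set,
identified only up to the anchor.
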