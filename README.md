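# kmopt

Meta-analyses of time-to-event outcomes need the log hazard ratio, ln(HR),
and its variance from every study — but many papers, especially in prognostic
research, publish only a Kaplan-Meier (KM) plot and a log-rank P value: no
hazard ratio, no confidence interval, no numbers at risk under the plot.
`kmopt` reconstructs the two-arm KM life table behind such a plot from
digitized (time, survival) points and recovers ln(HR) and var ln(HR) for use
in aggregate-data meta-analysis, for systematic reviewers and
meta-analysts who would otherwise have to discard those studies.

## The method

The KM estimator steps down by the conditional event fraction at each
timepoint,

    S(t_j) = S(t_{j-1}) (1 - e_j / n_j),

so a digitized curve fixes the event counts *given* the at-risk numbers —
which depend on the unknown censor counts `c_ij` per interval and arm.
Inverting the step gives `e_j = n_j (1 - S(t_j)/S(t_{j-1}))` with
`n_j = n_{j-1} - (c_{j-1} + e_{j-1})`. The published P value pins down the
log-rank chi-square

    X^2 = sum_i (O_i - E_i)^2 / E_i   (2 groups, 1 df),

where `E_ij = (e_1j + e_2j) n_ij / (n_1j + n_2j)` is the null allocation of
events. `kmopt` treats the censor counts of both arms as the decision vector
of a constrained non-linear program — bounds `c >= 0`, per-arm accounting
`sum(c) + sum(e) = N_0`, at-risk counts non-negative, and the chi-square
anchored at `qchisq(1 - p, 1)` (an equality for an exact P; bracket
constraints for "< 0.01" or "ns" reporting) — and solves it with SLSQP using
analytic gradients. The reconstructed table then yields

    HR = (O1/E1) / (O2/E2),   var ln(HR) = 1/E1 + 1/E2,

the meta-analysis inputs. The anchoring P value must come from a log-rank or
Cox model, so the method inherits their proportional-hazards assumption.

The package also ships the full simulation machinery used to validate the
method and to decide **how many points to extract and where**: a two-arm
exponential/Weibull IPD generator with exact product-limit and log-rank
oracles, Monte-Carlo point-sampling experiments, and the practical placement
rule (one point per 2% survival drop, `recommend_times()`).

## Worked example

A synthetic "published study": 120 vs 118 patients, the plot digitized into
48 points (`inst/extdata/synthetic_example_points.csv`, generated by the
package's own simulator — the file name says synthetic because it is), and a
reported chi-square of 22.84:

```r
library(kmopt)
pts <- read_points_csv(system.file("extdata", "synthetic_example_points.csv",
                                   package = "kmopt"))
fit <- solve_from_points(pts, parse_pvalue("chisq:22.84"), n1_0 = 120, n2_0 = 118)
print(fit)
```

```
KM reconstruction (exact P value): converged, anchor matched after 7 iterations (start 1)
  residuals: eq 4.63e-17, ineq 0.00e+00, chisq 4.93e-12
Two-arm life-table summary
  O1 = 97.8675  E1 = 68.6964 | O2 = 52.2376  E2 = 81.4086
  HR (arm1 vs arm2) = 2.2202   ln(HR) = 0.7976   var ln(HR) = 0.02684
  chi-square (1 df) = 22.8400   P = 1.761e-06
```

Reading the output: the solver found a censor pattern that accounts for all
238 patients (`eq` residual ~1e-17), keeps every at-risk count non-negative,
and reproduces the published statistic to 5e-12. The reconstructed
`ln(HR) = 0.798` with `var ln(HR) = 0.0268` (95% CI for the HR: 1.61–3.06)
is the pair a meta-analyst would feed into an inverse-variance pool; the
generating truth for this cohort was ln(HR) = 0.784, an absolute error of
0.013. A P value given as text works the same way: `parse_pvalue("0.003")`,
`parse_pvalue("<0.01")`, `parse_pvalue("ns")` — the non-exact forms anchor
the statistic by inequality brackets instead of an equality, and are
noticeably less accurate (use them only when nothing better is published).

The same pipeline is scriptable from a shell via the installed `exec/kmopt`
entry point:

```sh
kmopt solve --points points.csv --n1 120 --n2 118 --p "chisq:22.84" \
      --out result.json --table table.csv
kmopt generate --out cohort.csv --truth truth.json --hr 2 --seed 1
kmopt simulate --scenario scenario.cfg --out summary.csv --seed 1
```

Exit codes: 0 success, 2 invalid input, 3 solver failure or an unattainable
published P value.

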