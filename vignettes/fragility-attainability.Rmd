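---
title: "Fragility-index attainability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragility-index attainability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragattain)
```

## The metric and the question

The fragility index (FI) of a two-arm trial with a binary outcome is the
minimum number of patients whose outcome must be changed from nonevent to
event — in the arm with fewer events, keeping the arm size fixed — to turn a
statistically significant two-sided Fisher exact result (p < 0.05) into a
nonsignificant one (p >= 0.05). A metric proposed as a universal reporting
standard should return a value for every valid input. The original FI does
not: for some valid baseline-significant tables the algorithm has no legal
first move, and for others every legal move pushes the p-value *away* from
the significance boundary until the arm is exhausted. `fragattain`
implements the original algorithm with these failure modes as first-class,
named outcomes, plus the machinery to enumerate and characterise them.

## The algorithm, precisely

For a table $\{a, b, c, d\}$ ($a, c$ events, $b, d$ nonevents in arms A and
B):

1. the baseline table must be nondegenerate (both arms nonempty, both
   outcome columns present) and significant (two-sided Fisher exact
   $p < \alpha$, default $\alpha = 0.05$);
2. select the arm with fewer events. Ties ($a = c$) are not evaluable: the
   definition provides no tie-break, and none is invented here;
3. repeatedly convert one nonevent to an event in the selected arm (events
   + 1, nonevents − 1; arm total fixed), recomputing the two-sided p after
   each step. **The arm is selected once at baseline and never
   re-evaluated**, even if its event count overtakes the other arm's — the
   published toggle trajectories require exactly this behaviour;
4. the FI is the number of steps at the first $p \ge \alpha$. If the
   selected arm has no nonevents at baseline the outcome is *not attainable*
   with mechanism `no_legal_move`; if toggles run out with every $p$ still
   below $\alpha$ it is *not attainable* with mechanism `path_exhausted`.

`fragility()` returns this as a classed object with the full toggle
trajectory; `evaluability()`, `select_arm()` and `toggle()` expose the
individual steps.

## The exact-test engine

All p-values come from one engine: the two-sided Fisher exact test computed
from the hypergeometric distribution. For margins $(r_1, r_2, k)$ the point
masses over the support are computed in log space, shifted by their maximum,
exponentiated and normalized to sum to one; the two-sided p is the sum, in
support order, of the masses not exceeding the observed one with relative
tolerance $1 + 10^{-7}$ (the minimum-likelihood convention of mainstream
exact-test implementations, which reproduces all published p-values used
here: 0.0429, 0.0487, 0.0116, 0.016). A cached cumulative log-factorial
table backs `point_probability()`, the closed-form hypergeometric mass.
p-values are held at full double precision; 4-decimal rounding happens only
in reports.

### Boundary tables and exact arbitration

Complete enumeration exposes a subtlety no floating-point implementation
can dodge: tables whose two-sided p equals $\alpha$ *exactly as a rational
number*. At $\alpha = 0.05$ the table $\{0, 1, 19, 0\}$ has
$p = 1/20$ exactly; there are two such tables at $N = 20$, six at $N = 25$,
six at $N = 40$ and eight at $N = 60$. Whether a double-precision p lands an
ulp above or below 0.05 for these tables is platform rounding noise, and
published counts computed this way inherit that noise.

`fragattain` therefore arbitrates every significance comparison that falls
within $10^{-10}$ of $\alpha$ in exact integer arithmetic: the comparison
$p < \alpha$ is decided as $10^6 S < A\, C(N, k)$ with
$S = \sum C(r_1, x) C(r_2, k - x)$ over the qualifying support and
$A = 10^6 \alpha$ ($\alpha$ is read as a decimal fraction with up to six
places), using a small built-in big-integer layer (`R/exact.R`). A table
with $p = 1/20$ is thus *not significant* at $\alpha = 0.05$ — the
mathematically correct reading of "p < 0.05" — on every platform. The
$10^{-10}$ window is far wider than the engine's error (~$10^{-14}$) and far
narrower than the spacing of distinct attainability-relevant p-values near
0.05 in this range, so the arbitration never touches a table the float
comparison already decides correctly.

The practical consequence: all *unattainability* counts produced by the
enumeration are platform-independent, while published per-N
total-significant and attainable counts that included boundary tables (the
inflation is at most a handful of tables at N = 20, 40 and 60) differ from
the exact classification by exactly those knife-edge tables.

## Complete enumeration

`fragility_enumeration(n_min, n_max)` classifies every nondegenerate table
at each total sample size N. Tables are parameterised by margin signature
$(r_1, k)$ plus the observed cell $a$, and the engine computes the two-sided
p for an entire support in one pass, so each margin signature — shared by
every table and toggle step that traverses it — is priced once. The lookup
covers $k = N$ (a toggled table may empty the nonevent column, where p = 1).
The per-table walk then reads the forced path out of the lookup. The full
N = 2–60 study (616,705 nondegenerate tables, ~300,000 of them significant)
runs in well under a minute on one core; memory stays in the tens of
megabytes because per-table records are kept only for baseline-significant
tables, matching the bookkeeping the analysis needs.

Per-N summaries report total significant, attainable, unattainable,
tied-event exclusions, and the rate
`unattainable / (attainable + unattainable)`; `min_cell_tally()` and
`mechanism_tally()` aggregate the unattainable records. Every
`no_legal_move` table necessarily has a zero cell (the selected arm's
nonevent cell); `path_exhausted` tables need not — the majority of
unattainable cases have no zero cell at all, which is the substantive point:
nonattainability is not a zero-cell artifact and would not be cured by
continuity corrections.

## Association analysis

`predictor_correlations()` computes Spearman rank correlations (midrank
ties, via `stats::cor`; the binary nonattainability indicator enters as 0/1
ranks — no point-biserial shortcut) between nonattainability and two
structural predictors: allocation imbalance, taken as the ratio of the
larger to the smaller arm size so the predictor is orientation-free, and
total sample size. Only evaluable tables (attainable or unattainable) enter;
tied-event exclusions do not, and the JSON report flags this scope.
Confidence intervals use the Fisher z-transform with standard error
$1/\sqrt{n - 3}$ — a pragmatic choice for a rank correlation at this scale,
adequate because $n$ is large and only the interval's order of magnitude
matters here.

One caution for users comparing against published figures: with these
records the imbalance correlation is r = 0.324, while the
nonattainability–sample-size correlation is r = 0.055. The Spearman
correlation *between the two predictors themselves* (sample size vs
imbalance) is r = 0.015 with Fisher-z CI [0.011, 0.019]; a published
sample-size association equal to that value to every printed digit is
almost certainly a transposed correlation-matrix cell rather than a
different analysis population — no population choice we tried (evaluable
only, all significant, all nondegenerate) moves the as-defined correlation
to 0.015.

## Random-table generator

`random_tables(n_tables, n_total_max, seed)` draws, per table, a total N
uniformly from `2:n_total_max`, then a uniform composition of N into four
cells (stars and bars), rejecting degenerate quadruples — i.e. a uniform
draw over the valid tables at each drawn N. It emulates the *combinatorial*
table space, which is what the attainability machinery quantifies over; it
does not emulate clinical trial data (real trials have correlated arm
sizes, event rates far from uniform, and N in the thousands), so
property-test passes say the algorithm is implemented correctly, not that
any clinical prevalence estimate follows. The generator runs on a local
Mersenne-Twister stream and restores the caller's RNG state.

## Numerical and design choices

* **Significance is strict** (`p < alpha`), nonsignificance inclusive
  (`p >= alpha`), as in the original definition.
* **alpha** defaults to 0.05 and is a genuine parameter; all published
  reference values use 0.05.
* **Trajectories are always retained** (at most arm-size + 1 entries) so
  reports and tests can replay the path.
* **Enumeration order** is lexicographic in (a, b, c); counts are
  order-invariant but fixed order makes record files byte-reproducible.
* **Report formatting** is fixed: p-values to 4 decimals, rates to one
  decimal of percent, so repeated runs produce identical bytes.
* **Exit codes** (CLI): 0 attainable, 2 not attainable, 3 not evaluable,
  64 usage error — nonattainability is a named result, never a generic
  failure.
* **Degenerate inputs**: `fragility()` is total (returns `not_evaluable`
  with a reason); the bare test functions raise errors naming the offending
  margin.

## Problem sizes used in the tests

The shipped test suite exercises: exact-oracle equivalence of the p-value
engine on every nondegenerate table with N <= 12 (4,300 tables, against a
direct binomial-coefficient oracle) and spot agreement with
`stats::fisher.test`; an independent step-by-step replay of the FI
algorithm on all evaluable tables at N in {8, 12, 16, 20}; path-conservation
invariants on 10,000 seeded random tables with N <= 60; the full N = 2–60
enumeration against the published per-N rows, cumulative totals, mechanism
split and minimum-cell distribution; and byte-level determinism of all
written reports.

## Known limitations

* Only 2×2 tables under the two-sided Fisher exact test are in scope — the
  conditions under which the original FI was defined. Alternative metrics
  (bidirectional toggling, global reallocation, fragility quotients,
  reverse FI for nonsignificant results) are out of scope.
* Tied-event tables are excluded, mirroring the metric's own gap, not
  resolving it.
* Enumeration beyond the requested `n_max` (and asymptotics of the
  unattainability rate) is not attempted.
* Exact boundary arbitration assumes alpha is a decimal fraction with at
  most six places; other alphas fall back to the floating comparison.
* The big-integer arbitration is exercised at enumeration scale (N <= 60
  plus the packaged trial tables); for user tables with N in the tens of
  thousands whose path p lands within 1e-10 of alpha it would be slow,
  though such inputs are vanishingly rare.
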