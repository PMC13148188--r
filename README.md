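# fragattain

Fragility-index attainability analysis for 2×2 clinical-trial tables.

## The problem

The fragility index (FI) of a two-arm trial with a binary outcome is the
minimum number of patients whose outcome must change from nonevent to event
— in the arm with fewer events, keeping the arm size fixed — to turn a
significant two-sided Fisher exact result (p < 0.05) into a nonsignificant
one (p ≥ 0.05). It is widely reported, and has been proposed as a mandatory
companion to the p-value.

But the FI, as originally defined, is a *partial function*: valid
baseline-significant tables exist for which the algorithm produces no finite
value. For the table {a, b, c, d} = {3, 0, 4, 11} (a, c events; b, d
nonevents), p = 0.0429 and the arm with fewer events is arm A — which has
zero nonevents, so no legal move exists. For {9, 35, 8, 8} (p = 0.0487) the
selected arm B has eight nonevents, but every permitted toggle drives the
p-value *away* from 0.05 until the arm is exhausted. Calculators that treat
these cases as generic errors silently exclude real trials from fragility
summaries.

`fragattain` is for biostatisticians and methodologists who need the
original FI with honest semantics: every table gets a named outcome —
**attainable** (with the FI), **not attainable** (with the mechanism:
`no_legal_move` or `path_exhausted`), or **not evaluable** (not significant,
tied event counts, or degenerate) — plus the complete-enumeration and
association machinery to study how often and why nonattainability occurs.

## What is inside

* `fragility(x, alpha = 0.05)` — the original algorithm, returning a classed
  object with the full toggle trajectory; `print`, `summary`, `plot`
  methods; helpers `evaluability()`, `select_arm()`, `toggle()`.
* `two_sided_p()`, `point_probability()` — the exact-test engine
  (hypergeometric, log-space, minimum-likelihood two-sided convention;
  significance comparisons within 1e-10 of alpha are arbitrated in exact
  integer arithmetic so boundary tables with p exactly equal to alpha are
  classified identically on every platform).
* `fragility_enumeration(n_min, n_max)` — classifies every nondegenerate
  table at each total sample size; per-N summaries, per-table records,
  `min_cell_tally()`, `mechanism_tally()`, CSV/JSON report writers.
* `predictor_correlations()`, `spearman_ci()` — Spearman associations
  (midranks, Fisher-z intervals) between nonattainability and allocation
  imbalance / total sample size.
* `fi_registry()` — packaged counterexamples and published-trial tables
  (FINEARTS-HF, ISCHEMIA, FRESCO); `read_tables_csv()` /
  `write_tables_csv()` for batch work; `random_tables()` for property
  testing.
* A command line: `fi`, `batch`, `enumerate`, `associate`, `report`
  (script in `inst/cli/`, logic in `cli_main()`; exit codes 0 = attainable,
  2 = not attainable, 3 = not evaluable, 64 = usage).

## Worked example

```r
library(fragattain)
summary(fragility(c(9, 35, 8, 8)))
```

```
Fragility index (original algorithm, alpha = 0.05)
  table {a,b,c,d} = {9, 35, 8, 8}   N = 60
  baseline two-sided Fisher p = 0.0487
  status: NOT ATTAINABLE (path exhausted: arm B ran out of nonevents after 8 toggles with p still < 0.05)
  toggle trajectory (8 toggles):
    baseline {9,35,8,8}  p = 0.0487
    toggle  1 {9,35,9,7}  p = 0.0116
    toggle  2 {9,35,10,6}  p = 0.0039
    toggle  3 {9,35,11,5}  p = 0.0012
    toggle  4 {9,35,12,4}  p = 0.0002
    toggle  5 {9,35,13,3}  p = 0.0000
    ...
    toggle  8 {9,35,16,0}  p = 0.0000
```

The baseline is significant (0.0487 < 0.05), arm B has fewer events
(8 < 9), and each forced toggle raises arm B's event rate from 50% toward
100%, widening the between-arm disparity — the p-value moves monotonically
away from the boundary until the arm is exhausted. No finite FI exists.

The enumeration machinery quantifies how often this happens:

```r
e <- fragility_enumeration(2, 30)
e
```

```
Fragility-index enumeration, N = 2..30, alpha = 0.05
  14112 baseline-significant tables (13792 evaluable, 320 tied-excluded)
  FI unattainable: 520 of 13792 evaluable (3.8%)
  first unattainable case at N = 18
```

`summary(e)` gives the per-N rows (at N = 18: 324 significant, 314
attainable, 2 unattainable, 8 tied-excluded — a 0.6% unattainability rate),
`mechanism_tally(e)` splits the unattainable cases into the two mechanisms,
and `min_cell_tally(e)` shows that most path-exhausted tables contain no
zero cell at all.

From a shell:

```sh
$ fragattain fi 3 0 4 11
Fragility index (original algorithm, alpha = 0.05)
  table {a,b,c,d} = {3, 0, 4, 11}   N = 18
  baseline two-sided Fisher p = 0.0429
  status: NOT ATTAINABLE (no legal move: arm A has zero nonevents at baseline)
$ echo $?
2
```

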