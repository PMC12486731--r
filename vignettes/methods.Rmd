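---
title: "Methods: costing, outcome accumulation, frontier analysis and the synthetic trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: costing, outcome accumulation, frontier analysis and the synthetic trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceafrontier)
library(dplyr)
```

`ceafrontier` evaluates eight delivery strategies of a group CBT prevention
programme for child anxiety and depression from a health-service perspective.
This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The strategy space

Three binary delivery factors — format (long: 16 in-person child sessions, vs
hybrid: 8 in-person + 8 web-based), parental involvement (5 parent sessions
vs brochure) and measurement feedback (MFS vs none) — define a 2×2×2 grid of
eight strategies, labelled by three-letter codes (`strategy_grid()`).

## Micro-costing

Costs cover intervention delivery only (health-service perspective): no
parental time, productivity losses or downstream service use, and no
discounting over the 62-week horizon. For one group,

* labour: each of `group_leaders` (default 2) works
  `child_sessions × (1h + 1h prep) + parent_sessions × (1.5h + 1h prep)`
  plus 8 h of MFS data review in feedback arms (1 h/week over the 8-week
  course), 4 h of supervision and 2 h of recruitment/screening, valued at the
  loaded hourly rate;
* materials: workbooks per group, NOK 1345 (brochure arm) or 2540 (parent
  session arm) — flat per group, since the trial's cost accounting does not
  scale them with group size;
* the MFS app, NOK 225 per group, feedback arms only;
* a flat NOK 1000 supervisor fee per group. Supervision thus appears twice by
  design — leader hours *and* the shared supervisor's fee — because both
  resources are really consumed.

The loaded hourly rate defaults to NOK 529 (school-health-nurse wage × 1.4
for social costs). The rate is taken as given — the published cost table
closes exactly with it — but a base wage can be supplied instead, in which
case the rate is derived with the 1.4 multiplier. Per-child cost divides by
the average observed group size of 5. Web-based session hosting in the hybrid
arm is assumed free of charge to the service (no platform fee appears in the
trial's cost accounting). All arithmetic is at full precision; display
rounding (whole NOK per group, one decimal per child) is left to the caller.

```{r}
cost_breakdown() |> select(code, hours_per_leader, per_group, per_child)
```

## Outcome accumulation

MASC (0–117, integer, lower better), SMFQ (0–26, integer, lower better) and
HRQoL utility (0–1, higher better) were measured at weeks 0, 12 and 62. The
accumulated score is the area under the piecewise-linear trajectory of the
*arm means*, in score-years with a 52-week year:

$$\mathrm{acc} = \frac{m_1+m_2}{2}\cdot\frac{12}{52}
             + \frac{m_2+m_3}{2}\cdot\frac{50}{52}.$$

Accumulated HRQoL is the QALYs accrued over the 62-week window (a constant
utility of 1 gives 62/52 ≈ 1.192 QALYs). Timepoints and the year denominator
are configurable (`interval_weeks`, `weeks_per_year`) but default to the
study design; 52, not 52.18, matches the formula as applied.

Summaries are available-case: a child missing at one timepoint is excluded
from that timepoint only, so per-timepoint Ns differ within an arm.
Accumulation therefore operates on per-timepoint arm means rather than
per-child trajectories; feeding `accumulate_outcomes()` a completer-only
subset of records gives the per-child sensitivity variant. The SD of a single
observation is reported as missing by default (`sd_single = 0` restores the
other convention). HRQoL utilities are consumed directly; the
instrument-to-utility scoring that produced them is external, and
`map_hrqol_utility()` is the pass-through hook for plugging in an alternative
mapping.

A caveat for reconstruction exercises: published accumulated values were
computed from unrounded arm means. Recomputing them from means printed to two
decimals can differ by up to `0.005 × 62/52 ≈ 0.006` (the worst-case rounding
propagation through the trapezoid weights); `published_accumulated()`
therefore offers both the `"printed"` values and the `"recomputed"` ones.

## ICERs, dominance and the frontier

For strategies ordered by cost, the incremental cost-effectiveness ratio of
strategy *j + 1* versus *j* is
$\mathrm{ICER} = \Delta C_{j+1,j} / \Delta E_{j+1,j}$, with effects oriented
so that larger is healthier (symptom scores are negated). For MASC/SMFQ the
unit is NOK per point of improvement; for QALYs, NOK per QALY gained.

`cea_analysis()` classifies each strategy:

1. sort by cost ascending; equal costs tie-break to the better effect, and
   exact (cost, effect) ties collapse to one frontier representative;
2. **dominated** — some other strategy has no higher cost and no worse
   effect, with at least one strict inequality (weak dominance is included:
   the published analysis never encounters ties, but the algorithm must be
   total);
3. **extended dominated** — among the survivors, any strategy whose incoming
   adjacent ICER is at least its outgoing one is removed, repeating until the
   ICER sequence strictly increases;
4. survivors form the frontier, equivalently the lower-right convex hull in
   (effect, cost) space — the test suite checks the algorithm against an
   independent brute-force blend-dominance oracle on random instances.

Negative adjacent ICERs (extra cost, worse health) are reported as-is on
dominated rows. An ICER with zero effect difference is `Inf` ("undefined"),
not an error; such a strategy is weakly dominated and never reaches the
frontier. ICERs are kept at full precision; the published tables round
*inputs* (integer NOK costs, two- or three-decimal accumulated values), so
`cea_inputs(round_inputs = TRUE)` — the default — reproduces the published
footnote arithmetic, and `round_inputs = FALSE` gives the full-precision
variant.

QALY frontier ICERs are compared with the Norwegian severity-dependent
willingness-to-pay range, NOK 275,000–825,000 per QALY
(`cet_verdict()`: at or below the lower bound / within / above). No such
threshold exists for symptom-score outcomes, so their verdicts are
suppressed with a note.

One published label is internally inconsistent: in the anxiety table, LLN is
marked extended-dominated although it is strictly dominated by SLF (higher
cost, worse accumulated MASC). The classification algorithm reproduces the
published *frontier membership* everywhere and the published labels
elsewhere; that single label is treated as a typo and tested by membership
only.

## The synthetic trial generator

No individual-level data are distributed with the trial, so
`simulate_trial()` emulates the published statistical structure:

* eight arms with the published per-arm/timepoint Ns (T1 total 701, retention
  633 and 564), means and SDs for the three measures;
* pooled baseline cross-measure correlations 0.438 (MASC–SMFQ), −0.368
  (MASC–HRQoL), −0.597 (SMFQ–HRQoL);
* bounded scales, integer-valued symptom scores, monotone missed-visit
  dropout (missing at week 12 implies missing at week 62), 59.8% girls, mean
  age 10.5 on 8–12.

Generation is a Gaussian copula. Per arm, a 9-dimensional latent normal
(3 measures × 3 timepoints) is drawn with a separable correlation matrix:
the baseline cross-measure correlations combined with an AR(1)
autocorrelation across timepoints. The within-measure autocorrelation is not
published; the default `rho_time = 0.6` is a typical value for repeated
psychometric sum scores over 3–12 months, is configurable, and is flagged as
an assumption in every calibration report. Cross-measure correlations at the
later timepoints are likewise not published and reuse the baseline structure.
The assembled matrix is checked for positive semi-definiteness and repaired
to the nearest PSD matrix if needed (the default targets need no repair; the
repair magnitude is logged and large repairs are an error). Dropout is
completely at random within an arm with counts fixed to the published
retention; arm-level Ns follow the anxiety-measure N rows, whose T1 column
sums to 701 — the one-to-two-child differences between measures within a
published cell (item-level missingness) are not simulated.

Margins are then mapped to their targets. With `empirical = TRUE` (default)
the *final* observed values are moment-matched: after dropout, clipping to
the scale bounds and rounding of integer scales, each arm/measure/timepoint
cell's available-case mean and SD equal their targets as closely as the
discrete scale allows (a scale-fitting pass followed by bisection on the
location shift, whose post-rounding mean is monotone; the residual is about
one part in the cell's n, ≈ 0.01–0.02 score points at the default sizes).
This is the `MASS::mvrnorm(empirical = TRUE)` convention, chosen because the
downstream CEA operates on arm means and the study conditions are defined by
the published moments: the generator's job is to reproduce those conditions,
not to add sampling noise on top of them. With `empirical = FALSE` targets
are population parameters, sample moments fluctuate with ordinary
Monte-Carlo noise, and clipping-induced mean bias is corrected only when it
exceeds `mean_correction = 0.5` score points (it stays an order of magnitude
below that threshold at the published means and SDs; the measured shift is
reported either way).

What passing tests on synthetic data therefore show: the pipeline's
arithmetic — summaries, accumulation, costing, frontier construction — is
correct for data with the published first and second moments, correlation
structure and missingness pattern. What they cannot show: robustness to
features the generator does not emulate — informative dropout, skewed or
floor-heavy score distributions beyond clipping, school-level clustering,
wave effects, or per-measure item missingness. Conclusions about the real
trial rest on the published arm-level statistics, which the published-means
mode consumes directly.

## Numerical and design choices

* Currency is NOK at the trial's price level; no discounting (62-week
  horizon) and no uncertainty analysis — the evaluation is of mean values by
  design, so no probabilistic sensitivity analysis is offered.
* `run_all()` is deterministic given `seed`; the generator is a pure
  function of seed and configuration.
* Degenerate inputs are defined, not accidental: zero target SD puts every
  child at the (clipped, rounded) arm mean; a single strategy is its own
  frontier with no ICER; empty inputs, duplicate strategy codes, retention
  exceeding arm size, division by a zero group size and infeasible
  correlation targets are errors with named causes.
* Test problem sizes: golden reproductions run on the eight published
  strategies; the frontier algorithm is checked against the brute-force
  oracle on 1,000 random instances of up to 8 strategies; generator
  calibration uses the full 701-child configuration, and the
  pipeline-vs-published-frontier agreement is measured over 100 seeds with
  agreement required in at least 95% (the anxiety frontier hinges on an 0.09
  accumulated-point gap, so occasional flips under the integer-scale residual
  are expected); population-mode coverage uses 200 replicates of a small
  two-arm trial.

## Limitations

The package evaluates the eight delivery strategies against each other; there
is no no-intervention comparator, so ICERs are relative to the cheapest
strategy, not to doing nothing. Costs are strategy-level constants —
individual-level cost variation (and hence cost uncertainty) is out of scope.
The QALY measure inherits whatever systematic error the external
instrument-to-utility mapping carries. Extended dominance assumes strategies
are divisible or mixable at the margin, the standard convention for frontier
construction.
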