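# ceafrontier

Trial-based cost-effectiveness analysis of alternative delivery strategies of
a group cognitive-behavioural prevention programme for child anxiety and
depression, from a health-service perspective.

School-based indicated prevention for children (ages 8–12) with elevated
anxiety or depressive symptoms can be delivered in many ways. An optimisation
trial crossed three binary delivery factors — delivery format (16 in-person
child group sessions vs a hybrid of 8 in-person + 8 web-based), parental
involvement (5 parent group sessions vs a brochure), and a measurement
feedback system (MFS feedback to group leaders vs none) — giving eight
strategies, coded `SLN` … `LHF` (hybrid/long, low/high parental involvement,
no-feedback/feedback). `ceafrontier` implements the full economic evaluation
of such a design for analysts in health economics and child mental health
services research:

* **Micro-costing.** Per-group delivery cost from resource quantities and
  unit costs: `labor = hours_per_leader × loaded_rate × leaders`, plus
  workbooks, the MFS app and a flat supervision fee;
  `per_child = per_group / group_size`.
* **Outcome accumulation.** Repeated scores (MASC anxiety 0–117, SMFQ
  depression 0–26, HRQoL utility 0–1) at weeks 0, 12 and 62 are summarised as
  the area under the piecewise-linear trajectory,

  ```
  accumulated = (m1 + m2)/2 · 12/52 + (m2 + m3)/2 · 50/52
  ```

  which for HRQoL is the QALYs accrued over the 62-week window.
* **ICERs and the frontier.** Strategies ordered by cost; incremental
  cost-effectiveness ratios `ICER = ΔC / ΔE` with effects oriented so that
  larger is healthier; strategies classified as *dominated* (another strategy
  is no costlier and no less effective, with one strict), *extended
  dominated* (pruned until adjacent frontier ICERs strictly increase), or on
  the *frontier*; QALY frontier ICERs compared with the Norwegian
  willingness-to-pay range of NOK 275,000–825,000 per QALY.
* **Synthetic trial generator.** A Gaussian-copula simulator calibrated to
  the published per-arm/timepoint means, SDs and retention counts (total
  N = 701 with monotone dropout) and the published baseline cross-measure
  correlations, so the whole pipeline runs and is tested without access to
  individual-level trial data.

## Worked example

```r
library(ceafrontier)

costs <- cost_breakdown()                      # micro-costing, default config
fit <- cea_analysis(
  cea_inputs(costs, published_accumulated(), "hrqol"),
  measure = "hrqol"
)
fit
#> Cost-effectiveness analysis (hrqol)
#> Frontier: SLN -> LLN
#>
#> # A tibble: 8 × 10
#>   strategy  cost incr_cost accumulated incr_effect     icer classification
#> 1 SLN       5124        NA       0.938    NA            NA  frontier
#> 2 SLF       6862      1738       0.949     0.0110   158000. extended_dominated
#> 3 SHN       8008      1146       0.958     0.00900  127333. extended_dominated
#> 4 LLN       8510       502       0.973     0.0150    33467. frontier
#> 5 SHF       9746      1236       0.936    -0.0370   -33405. dominated
#> 6 LLF      10248       502       0.969     0.0330    15212. dominated
#> 7 LHN      11394      1146       0.967   -0.00200 -573000. dominated
#> 8 LHF      13132      1738       0.955   -0.0120  -144833. dominated
```

Reading the table: the cheapest strategy `SLN` (hybrid format, parental
brochure, no feedback) costs NOK 5124 per child and yields 0.938 accumulated
QALYs. Moving up the frontier to `LLN` (the full 16-session format) buys
0.035 extra QALYs for NOK 3386 more, a frontier ICER of

```r
fit$frontier$icer[-1]
#> [1] 96742.86
fit$frontier$cet_verdict[-1]
#> [1] "below_lower_bound"
```

— well below the lowest Norwegian threshold of NOK 275,000 per QALY, so the
more intensive format is good value. Every other strategy is dominated or
extended dominated. `tidy()`, `glance()` and `autoplot()` give the table, a
one-row summary and the frontier figure. The same call with
`measure = "masc"` identifies the anxiety frontier `SLN → SLF → LLF` (ICERs
281 and 37,622 NOK per MASC point), and `measure = "smfq"` the depression
frontier `SLN → LLN` (1620 NOK per SMFQ point).

An end-to-end run from simulated individual records:

```r
res <- run_all("outputs", seed = 42)           # simulate -> summarise ->
names(res$cea)                                 # accumulate -> cost -> CEA
#> [1] "masc"  "smfq"  "hrqol"
```

writes the records, calibration report, per-arm summaries, cost table, three
CEA tables, frontier JSONs and plot data to `outputs/`. Use
`run_all(..., published_means = TRUE)` to reproduce the published arm-level
analysis exactly.

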