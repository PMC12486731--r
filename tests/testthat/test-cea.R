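test_that("effects are oriented so that larger always means healthier", {
  expect_equal(orient_effect(72.98, "masc"), -72.98)
  expect_equal(orient_effect(11.84, "smfq"), -11.84)
  expect_equal(orient_effect(0.938, "hrqol"), 0.938)
  # improvement between strategies in oriented units
  expect_equal(orient_effect(9.75, "smfq") - orient_effect(11.84, "smfq"),
               2.09)
})

test_that("pairwise ICERs reproduce the published footnote arithmetic", {
  sln_masc <- data.frame(strategy = "SLN", cost = 5124, effect = -72.98)
  slf_masc <- data.frame(strategy = "SLF", cost = 6862, effect = -66.79)
  llf_masc <- data.frame(strategy = "LLF", cost = 10248, effect = -66.70)
  expect_equal(round(icer(sln_masc, slf_masc)), 281)
  expect_equal(round(icer(slf_masc, llf_masc)), 37622)

  sln_smfq <- data.frame(strategy = "SLN", cost = 5124, effect = -11.84)
  lln_smfq <- data.frame(strategy = "LLN", cost = 8510, effect = -9.75)
  expect_equal(round(icer(sln_smfq, lln_smfq)), 1620)

  # equal effects: undefined (infinite) price per unit of improvement
  same <- data.frame(strategy = "B", cost = 9000, effect = -11.84)
  expect_equal(icer(sln_smfq, same), Inf)
  expect_error(icer(sln_smfq, sln_smfq), "itself")
  expect_error(icer(lln_smfq, sln_smfq), "costlier")
})

test_that("published frontiers and incremental columns are reproduced", {
  fits <- lapply(c("masc", "smfq", "hrqol"), function(m) {
    cea_analysis(published_inputs(m), measure = m)
  })
  names(fits) <- c("masc", "smfq", "hrqol")

  expect_equal(fits$masc$frontier$strategy, c("SLN", "SLF", "LLF"))
  expect_equal(fits$smfq$frontier$strategy, c("SLN", "LLN"))
  expect_equal(fits$hrqol$frontier$strategy, c("SLN", "LLN"))

  for (fit in fits) {
    expect_equal(fit$table$strategy,
                 c("SLN", "SLF", "SHN", "LLN", "SHF", "LLF", "LHN", "LHF"))
    expect_equal(fit$table$incr_cost[-1],
                 c(1738, 1146, 502, 1236, 502, 1146, 1738))
  }

  expect_equal(round(fits$masc$frontier$icer[-1]), c(281, 37622))
  expect_equal(round(fits$smfq$frontier$icer[-1]), 1620)
  expect_equal(round(fits$hrqol$frontier$icer[-1]), 96743)

  # classifications match the published labels (SMFQ/QALY tables; the
  # anxiety table's label for LLN is inconsistent with its own dominance
  # definition, so only frontier membership is asserted there)
  smfq_class <- setNames(fits$smfq$table$classification,
                         fits$smfq$table$strategy)
  expect_equal(smfq_class[["SLF"]], "extended_dominated")
  expect_equal(smfq_class[["SHN"]], "extended_dominated")
  expect_equal(unname(smfq_class[c("SHF", "LLF", "LHN", "LHF")]),
               rep("dominated", 4))
  qaly_class <- setNames(fits$hrqol$table$classification,
                         fits$hrqol$table$strategy)
  expect_equal(unname(qaly_class[c("SLF", "SHN")]),
               rep("extended_dominated", 2))

  # published negative adjacent ICERs (worse health at extra cost)
  masc_icer <- setNames(fits$masc$table$icer, fits$masc$table$strategy)
  expect_equal(round(masc_icer[["SHN"]]), -205)
  expect_equal(round(masc_icer[["SHF"]]), -448)
})

test_that("single and duplicate strategies are handled at the edges", {
  single <- cea_analysis(
    data.frame(strategy = "SLN", cost = 5124, accumulated = 0.938),
    measure = "hrqol"
  )
  expect_equal(single$frontier$strategy, "SLN")
  expect_true(is.na(single$frontier$icer))
  expect_equal(single$table$classification, "frontier")

  expect_error(
    cea_analysis(data.frame(strategy = c("A", "A"), cost = c(1, 2),
                            accumulated = c(1, 2)), "hrqol"),
    "Duplicate"
  )
  expect_error(cea_analysis(data.frame(), "hrqol"), "at least one")

  # exact (cost, effect) ties collapse to one frontier representative
  tied <- cea_analysis(
    data.frame(strategy = c("A", "B", "C"), cost = c(100, 100, 200),
               accumulated = c(0.5, 0.5, 0.9)),
    measure = "hrqol"
  )
  expect_equal(sum(tied$table$classification == "frontier"), 2)
  expect_equal(tied$table$classification[tied$table$strategy == "B"],
               "dominated")
})

test_that("the frontier matches the brute-force blend-dominance oracle", {
  set.seed(5)
  for (rep in 1:250) {
    n <- sample(1:8, 1)
    inst <- random_instance(n)
    fit <- cea_analysis(inst, measure = "hrqol")
    algo <- sort(fit$frontier$strategy)
    oracle <- sort(inst$strategy[oracle_frontier(inst$cost,
                                                 orient_effect(inst$accumulated,
                                                               "hrqol"))])
    expect_equal(algo, oracle)
  }
})

test_that("frontier ICERs strictly increase and members are undominated", {
  set.seed(6)
  instances <- c(
    lapply(1:30, function(i) random_instance(sample(2:8, 1))),
    lapply(c("masc", "smfq", "hrqol"), published_inputs)
  )
  measures <- c(rep("hrqol", 30), "masc", "smfq", "hrqol")
  for (k in seq_along(instances)) {
    fit <- cea_analysis(instances[[k]], measure = measures[k])
    icers <- fit$frontier$icer[-1]
    if (length(icers) > 1) {
      expect_true(all(diff(icers) > 0))
    }
    # pairwise dominance soundness
    tab <- fit$table
    eff <- orient_effect(tab$accumulated, measures[k])
    for (i in which(tab$classification == "frontier")) {
      dominated <- any(tab$cost <= tab$cost[i] & eff >= eff[i] &
                         (tab$cost < tab$cost[i] | eff > eff[i]))
      expect_false(dominated)
    }
  }
})

test_that("deleting an off-frontier strategy leaves the frontier unchanged", {
  set.seed(7)
  for (rep in 1:25) {
    inst <- random_instance(sample(3:8, 1))
    fit <- cea_analysis(inst, measure = "hrqol")
    off <- fit$table$strategy[fit$table$classification != "frontier"]
    for (s in off) {
      refit <- cea_analysis(inst[inst$strategy != s, ], measure = "hrqol")
      expect_equal(refit$frontier$strategy, fit$frontier$strategy)
    }
  }
})

test_that("negating outcomes and flipping the benefit direction is a no-op", {
  set.seed(8)
  for (rep in 1:25) {
    inst <- random_instance(sample(2:8, 1))
    up <- cea_analysis(inst, measure = "hrqol")      # higher is better
    flipped <- inst
    flipped$accumulated <- -inst$accumulated
    down <- cea_analysis(flipped, measure = "smfq")  # lower is better
    expect_equal(down$frontier$strategy, up$frontier$strategy)
    expect_equal(down$frontier$icer, up$frontier$icer)
    expect_equal(down$table$classification, up$table$classification)
  }
})

test_that("threshold verdicts bracket the QALY willingness-to-pay range", {
  expect_equal(cet_verdict(c(NA, 96743, 275000, 500000, 825000, 900000)),
               c(NA, "below_lower_bound", "below_lower_bound",
                 "within_range", "within_range", "above_upper_bound"))
  expect_error(cet_verdict(1, cet = c(2, 1)), "increasing")

  qaly <- cea_analysis(published_inputs("hrqol"), measure = "hrqol")
  expect_equal(qaly$frontier$cet_verdict[-1], "below_lower_bound")
  # no threshold is defined for symptom scores
  masc <- cea_analysis(published_inputs("masc"), measure = "masc")
  expect_true(all(is.na(masc$frontier$cet_verdict)))
  expect_match(attr(masc$frontier, "cet_note"), "No cost-effectiveness")
})

test_that("tidy, glance and autoplot expose the analysis", {
  fit <- cea_analysis(published_inputs("hrqol"), measure = "hrqol")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8)
  expect_equal(td$measure[1], "hrqol")
  gl <- glance(fit)
  expect_equal(gl$n_frontier, 2L)
  expect_equal(gl$n_extended_dominated, 2L)
  expect_equal(gl$cheapest, "SLN")
  expect_equal(round(gl$max_frontier_icer), 96743)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
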