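test_that("strategy grid is a bijection between codes and factor triples", {
  grid <- strategy_grid()
  expect_equal(nrow(grid), 8)
  expect_equal(anyDuplicated(grid$code), 0)
  expect_equal(anyDuplicated(grid[c("delivery", "parental", "feedback")]), 0)
  sln <- strategy_from_code("SLN")
  expect_equal(sln$delivery, "hybrid")
  expect_equal(sln$parental, "low")
  expect_equal(sln$feedback, "none")
  lhf <- strategy_from_code("LHF")
  expect_equal(lhf$delivery, "long")
  expect_equal(lhf$parental, "high")
  expect_equal(lhf$feedback, "feedback")
  expect_error(strategy_from_code("XXX"), "Unknown strategy code")
})

test_that("session, preparation and total leader hours follow the profile", {
  profiles <- resource_profiles()
  hours <- setNames(session_prep_hours(profiles), profiles$code)
  expect_equal(hours[["SLN"]], 16)
  expect_equal(hours[["SHN"]], 28.5)
  expect_equal(hours[["LHF"]], 44.5)
  total <- setNames(hours_per_group_leader(profiles), profiles$code)
  expect_equal(total[["SLN"]], 22)   # 16 + 0 + 4 + 2
  expect_equal(total[["LHF"]], 58.5) # 44.5 + 8 + 4 + 2

  empty <- profiles[1, ]
  empty$child_sessions <- 0L
  empty$parent_sessions <- 0L
  empty$mfs_review_hours <- 0
  empty$supervision_hours_per_leader <- 0
  empty$recruitment_hours_per_leader <- 0
  expect_equal(session_prep_hours(empty), 0)
  expect_equal(hours_per_group_leader(empty), 0)

  bad <- profiles
  bad$child_sessions[1] <- -1L
  expect_error(session_prep_hours(bad), "non-negative")
})

test_that("the published cost table is reproduced exactly", {
  costs <- cost_breakdown()
  expect_equal(costs$code, c("SLN", "SLF", "SHN", "LLN", "SHF", "LLF",
                             "LHN", "LHF"))
  expect_equal(costs$per_group,
               c(25621, 34310, 40041, 42549, 48730, 51238, 56969, 65658))
  expect_equal(round(costs$per_child, 1),
               c(5124.2, 6862.0, 8008.2, 8509.8, 9746.0, 10247.6,
                 11393.8, 13131.6))
  # internal consistency of the decomposition
  expect_equal(costs$per_group,
               costs$labor + costs$materials + costs$app + costs$supervision)
  expect_equal(costs$per_child, costs$per_group / costs$group_size)
  expect_equal(costs$labor,
               costs$hours_per_leader * 529 * costs$group_leaders)
})

test_that("all-zero unit costs give zero group cost", {
  zero <- default_unit_costs()
  zero[c("loaded_hourly_rate", "workbooks_low_parental",
         "workbooks_high_parental", "mfs_app", "supervision_fee")] <- 0
  zero$base_hourly_wage <- NULL
  costs <- cost_breakdown(unit_costs = zero)
  expect_equal(costs$per_group, rep(0, 8))
})

test_that("cost is monotone in resource quantities and unit costs", {
  set.seed(11)
  base <- cost_breakdown()$per_group
  for (rep in 1:20) {
    resources <- default_resources()
    field <- sample(c("prep_per_session", "mfs_review_hours",
                      "supervision_hours_per_leader",
                      "recruitment_hours_per_leader"), 1)
    resources[[field]] <- resources[[field]] + runif(1, 0, 5)
    up <- cost_breakdown(resource_profiles(resources = resources))$per_group
    expect_true(all(up >= base))

    costs <- default_unit_costs()
    cfield <- sample(c("loaded_hourly_rate", "workbooks_low_parental",
                       "mfs_app", "supervision_fee"), 1)
    costs[[cfield]] <- costs[[cfield]] + runif(1, 0, 500)
    up2 <- cost_breakdown(unit_costs = costs)$per_group
    expect_true(all(up2 >= base))
  }
})

test_that("the feedback increment is identical across delivery/parental cells", {
  costs <- cost_breakdown()
  per_group <- setNames(costs$per_group, costs$code)
  increments <- c(
    per_group[["SLF"]] - per_group[["SLN"]],
    per_group[["SHF"]] - per_group[["SHN"]],
    per_group[["LLF"]] - per_group[["LLN"]],
    per_group[["LHF"]] - per_group[["LHN"]]
  )
  expect_equal(increments, rep(8689, 4)) # 8 h x 529 NOK x 2 leaders + 225 app
})

test_that("per-child division validates the group size", {
  expect_equal(child_cost(25621, 5), 5124.2)
  expect_equal(child_cost(25621, 1), 25621)
  expect_error(child_cost(25621, 0), "at least 1")
})

test_that("profile/strategy mismatches are rejected with the field named", {
  profiles <- resource_profiles()
  broken <- profiles
  broken$mfs_review_hours[broken$code == "SLF"] <- 0
  expect_error(cost_breakdown(broken), "mfs_review_hours")
  broken2 <- profiles
  broken2$mfs_review_hours[broken2$code == "SLN"] <- 8
  expect_error(cost_breakdown(broken2), "mfs_review_hours")
})

test_that("the packaged cost config reproduces the default cost table", {
  cfg_path <- system.file("extdata", "cost_config.yaml",
                          package = "ceafrontier")
  cfg <- read_cost_config(cfg_path)
  costs <- cost_breakdown(resource_profiles(resources = cfg$resources),
                          cfg$unit_costs)
  expect_equal(costs, cost_breakdown())

  # roundtrip and derived loaded rate
  tmp <- tempfile(fileext = ".yaml")
  cfg$unit_costs$base_hourly_wage <- 400
  cfg$unit_costs$loaded_hourly_rate <- 560
  write_cost_config(cfg, tmp)
  again <- read_cost_config(tmp)
  expect_equal(again$unit_costs$loaded_hourly_rate, 560)
  cfg$unit_costs$loaded_hourly_rate <- 561
  write_cost_config(cfg, tmp)
  expect_error(read_cost_config(tmp), "loaded_hourly_rate")
})
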