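#' Default delivery resource assumptions
#'
#' Common resource-use assumptions for running one intervention group:
#' two group leaders per group, five children per group on average, one hour
#' of preparation per session, 90-minute parent sessions and 60-minute child
#' sessions, 4 hours of supervision and 2 hours of recruitment/screening per
#' group leader, and — in feedback strategies — one hour per week over the
#' 8-week intervention period to review measurement feedback data.
#'
#' @return A named list of resource quantities (durations in hours, counts
#'   dimensionless).
#' @export
default_resources <- function() {
  list(
    child_session_duration = 1.0,
    parent_session_duration = 1.5,
    prep_per_session = 1.0,
    mfs_review_hours = 8.0,
    supervision_hours_per_leader = 4.0,
    recruitment_hours_per_leader = 2.0,
    group_leaders = 2L,
    group_size = 5L
  )
}

#' Default unit costs (NOK, 2024 price level)
#'
#' Group-leader time is valued at the loaded hourly rate of a school health
#' nurse, NOK 529/hour (average hourly wage multiplied by 1.4 to cover social
#' costs). Per-group material costs: workbooks NOK 1345 (brochure-only
#' parental involvement) or NOK 2540 (parent group sessions), the measurement
#' feedback app NOK 225 (feedback strategies only), and a flat NOK 1000
#' supervisor fee per group (the supervisor's cost is shared across the group
#' leaders being supervised, on top of the leaders' own 4 supervision hours).
#'
#' @param base_hourly_wage optional base wage; when supplied, the loaded rate
#'   is `base_hourly_wage * social_cost_multiplier` instead of the default 529.
#' @return A named list of unit costs in NOK.
#' @export
default_unit_costs <- function(base_hourly_wage = NULL) {
  multiplier <- 1.4
  rate <- if (is.null(base_hourly_wage)) 529 else base_hourly_wage * multiplier
  list(
    base_hourly_wage = base_hourly_wage,
    social_cost_multiplier = multiplier,
    loaded_hourly_rate = rate,
    workbooks_low_parental = 1345,
    workbooks_high_parental = 2540,
    mfs_app = 225,
    supervision_fee = 1000
  )
}

validate_unit_costs <- function(costs) {
  monetary <- c("loaded_hourly_rate", "workbooks_low_parental",
                "workbooks_high_parental", "mfs_app", "supervision_fee")
  for (f in monetary) {
    if (is.null(costs[[f]]) || !is.numeric(costs[[f]]) || costs[[f]] < 0) {
      stop("Unit cost `", f, "` must be a non-negative number.", call. = FALSE)
    }
  }
  if (!is.null(costs$base_hourly_wage)) {
    expected <- costs$base_hourly_wage * costs$social_cost_multiplier
    if (abs(expected - costs$loaded_hourly_rate) > 1e-8) {
      stop("`loaded_hourly_rate` must equal base_hourly_wage * ",
           "social_cost_multiplier when a base wage is supplied.",
           call. = FALSE)
    }
  }
  invisible(costs)
}

#' Per-strategy resource profiles
#'
#' Expands the strategy grid into one resource profile per strategy: session
#' counts and durations, preparation time, feedback-review time (8 hours for
#' feedback strategies, 0 otherwise), supervision and recruitment hours, the
#' number of group leaders and the group size.
#'
#' @param strategies a strategy tibble as returned by [strategy_grid()] (or a
#'   subset of its rows).
#' @param resources a resource assumption list as from [default_resources()].
#' @return A tibble with one row per strategy and one column per resource
#'   quantity.
#' @examples
#' resource_profiles()
#' @export
resource_profiles <- function(strategies = strategy_grid(),
                              resources = default_resources()) {
  stopifnot(is.data.frame(strategies))
  profiles <- dplyr::mutate(
    strategies,
    child_session_duration = resources$child_session_duration,
    parent_session_duration = resources$parent_session_duration,
    prep_per_session = resources$prep_per_session,
    mfs_review_hours = ifelse(.data$feedback == "feedback",
                              resources$mfs_review_hours, 0),
    supervision_hours_per_leader = resources$supervision_hours_per_leader,
    recruitment_hours_per_leader = resources$recruitment_hours_per_leader,
    group_leaders = resources$group_leaders,
    group_size = resources$group_size
  )
  validate_profiles(profiles)
  profiles
}

validate_profiles <- function(profiles) {
  qty <- c("child_sessions", "parent_sessions", "child_session_duration",
           "parent_session_duration", "prep_per_session", "mfs_review_hours",
           "supervision_hours_per_leader", "recruitment_hours_per_leader",
           "group_leaders", "group_size")
  missing <- setdiff(qty, names(profiles))
  if (length(missing) > 0) {
    stop("Resource profile is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in qty) {
    if (any(!is.finite(profiles[[f]]) | profiles[[f]] < 0)) {
      stop("Resource quantity `", f, "` must be non-negative and finite.",
           call. = FALSE)
    }
  }
  if (any(profiles$group_leaders < 1)) {
    stop("`group_leaders` must be at least 1.", call. = FALSE)
  }
  if (any(profiles$group_size < 1)) {
    stop("`group_size` must be at least 1.", call. = FALSE)
  }
  invisible(profiles)
}

#' Contact and preparation hours per group leader
#'
#' Each group leader attends every child and parent session and prepares one
#' hour per session, so the session workload is
#' `child_sessions * (duration + prep) + parent_sessions * (duration + prep)`.
#'
#' @param profiles a resource-profile tibble from [resource_profiles()].
#' @return Numeric vector of hours, one per profile row.
#' @examples
#' session_prep_hours(resource_profiles())
#' @export
session_prep_hours <- function(profiles) {
  validate_profiles(profiles)
  profiles$child_sessions *
    (profiles$child_session_duration + profiles$prep_per_session) +
    profiles$parent_sessions *
      (profiles$parent_session_duration + profiles$prep_per_session)
}

#' Total working hours per group leader
#'
#' Session and preparation hours plus feedback-data review, supervision and
#' recruitment/screening time.
#'
#' @inheritParams session_prep_hours
#' @return Numeric vector of hours, one per profile row.
#' @examples
#' hours_per_group_leader(resource_profiles())
#' @export
hours_per_group_leader <- function(profiles) {
  session_prep_hours(profiles) +
    profiles$mfs_review_hours +
    profiles$supervision_hours_per_leader +
    profiles$recruitment_hours_per_leader
}

#' Per-group and per-child delivery cost of each strategy
#'
#' Micro-costs one intervention group per strategy:
#' `labor = hours_per_leader * loaded_hourly_rate * group_leaders`,
#' `materials` = workbooks at the low- or high-parental rate,
#' `app` charged only in feedback strategies, plus the flat per-group
#' supervision fee. `per_group` is the exact sum of the four components and
#' `per_child = per_group / group_size` (kept at full precision; round only
#' for display).
#'
#' @inheritParams session_prep_hours
#' @param unit_costs a unit-cost list as from [default_unit_costs()].
#' @return A tibble with one row per strategy: the factor triple, the hours
#'   per group leader, the cost components `labor`, `materials`, `app`,
#'   `supervision`, and the totals `per_group` and `per_child` (NOK).
#' @examples
#' cost_breakdown()
#' @export
cost_breakdown <- function(profiles = resource_profiles(),
                           unit_costs = default_unit_costs()) {
  validate_profiles(profiles)
  validate_unit_costs(unit_costs)
  if (anyDuplicated(profiles$code) > 0) {
    stop("Duplicate strategy codes in `profiles`.", call. = FALSE)
  }
  # a feedback strategy without review hours (or vice versa) indicates a
  # mis-assembled profile rather than a scenario, so fail loudly
  mismatch <- profiles$feedback == "feedback" & profiles$mfs_review_hours <= 0
  if (any(mismatch)) {
    stop("Profile/strategy mismatch for ",
         paste(profiles$code[mismatch], collapse = ", "),
         ": field `mfs_review_hours` must be positive under feedback.",
         call. = FALSE)
  }
  mismatch <- profiles$feedback != "feedback" & profiles$mfs_review_hours > 0
  if (any(mismatch)) {
    stop("Profile/strategy mismatch for ",
         paste(profiles$code[mismatch], collapse = ", "),
         ": field `mfs_review_hours` must be 0 without feedback.",
         call. = FALSE)
  }

  out <- dplyr::mutate(
    profiles,
    session_hours = session_prep_hours(profiles),
    hours_per_leader = hours_per_group_leader(profiles),
    labor = .data$hours_per_leader * unit_costs$loaded_hourly_rate *
      .data$group_leaders,
    materials = ifelse(.data$parental == "high",
                       unit_costs$workbooks_high_parental,
                       unit_costs$workbooks_low_parental),
    app = ifelse(.data$feedback == "feedback", unit_costs$mfs_app, 0),
    supervision = unit_costs$supervision_fee,
    per_group = .data$labor + .data$materials + .data$app + .data$supervision,
    per_child = .data$per_group / .data$group_size
  )
  out <- dplyr::select(
    out, "code", "delivery", "parental", "feedback",
    "child_sessions", "parent_sessions", "session_hours", "hours_per_leader",
    "group_leaders", "group_size",
    "labor", "materials", "app", "supervision", "per_group", "per_child"
  )
  dplyr::arrange(out, .data$per_child, .data$code)
}

#' Cost per child from a per-group cost
#'
#' @param per_group numeric vector of per-group costs (NOK).
#' @param group_size number of children per group; must be at least 1.
#' @return Per-child cost `per_group / group_size`, full precision.
#' @examples
#' child_cost(25621, 5)
#' @export
child_cost <- function(per_group, group_size) {
  if (any(!is.finite(group_size)) || any(group_size < 1)) {
    stop("`group_size` must be at least 1 (division by zero groups).",
         call. = FALSE)
  }
  per_group / group_size
}

#' Read and write cost configuration files
#'
#' The cost model is fully described by a YAML file with two blocks,
#' `resources` and `unit_costs`; a packaged default reproducing the trial's
#' costing assumptions ships as
#' `system.file("extdata", "cost_config.yaml", package = "ceafrontier")`.
#'
#' @param path path to a YAML cost configuration.
#' @return `read_cost_config()`: a list with elements `resources` and
#'   `unit_costs`, validated; `write_cost_config()`: the path, invisibly.
#' @examples
#' cfg <- read_cost_config(
#'   system.file("extdata", "cost_config.yaml", package = "ceafrontier")
#' )
#' cost_breakdown(resource_profiles(resources = cfg$resources), cfg$unit_costs)
#' @export
read_cost_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$resources) || is.null(cfg$unit_costs)) {
    stop("Cost config must contain `resources` and `unit_costs` blocks.",
         call. = FALSE)
  }
  defaults <- default_resources()
  cfg$resources <- utils::modifyList(defaults, cfg$resources)
  cfg$unit_costs <- utils::modifyList(default_unit_costs(), cfg$unit_costs)
  validate_unit_costs(cfg$unit_costs)
  cfg
}

#' @param config a list with `resources` and `unit_costs` elements.
#' @rdname read_cost_config
#' @export
write_cost_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
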