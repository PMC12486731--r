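#' Assemble CEA inputs from costs and accumulated outcomes
#'
#' Joins the per-child cost of each strategy with its accumulated outcome for
#' one measure, in the layout [cea_analysis()] expects. Costs are rounded to
#' whole NOK when `round_inputs = TRUE` (the published tables' display
#' convention, which also governs the published footnote ICER arithmetic);
#' full-precision costs are used otherwise.
#'
#' @param costs a cost table from [cost_breakdown()] (columns `code`,
#'   `per_child`) or a data frame with columns `strategy` and `cost`.
#' @param accumulated an accumulated-outcome tibble from
#'   [accumulate_outcomes()] or [published_accumulated()].
#' @param measure which measure to select.
#' @param round_inputs round per-child costs to whole NOK.
#' @return A tibble with columns `strategy`, `cost`, `accumulated`, `measure`.
#' @export
cea_inputs <- function(costs, accumulated, measure,
                       round_inputs = TRUE) {
  if ("code" %in% names(costs) && "per_child" %in% names(costs)) {
    costs <- dplyr::transmute(costs, strategy = .data$code,
                              cost = .data$per_child)
  }
  if (!all(c("strategy", "cost") %in% names(costs))) {
    stop("`costs` must provide strategy and cost columns.", call. = FALSE)
  }
  measure <- measure_specs(measure)$measure
  acc <- dplyr::filter(accumulated, .data$measure == !!measure)
  if (nrow(acc) == 0) {
    stop("No accumulated outcomes for measure `", measure, "`.",
         call. = FALSE)
  }
  out <- dplyr::inner_join(costs, dplyr::select(acc, "strategy",
                                                "accumulated"),
                           by = "strategy")
  if (round_inputs) out$cost <- round(out$cost)
  dplyr::mutate(out, measure = measure)
}

#' Write the strategy cost table
#'
#' Computes the per-strategy cost decomposition and writes it as CSV in
#' ascending per-child cost order.
#'
#' @param out_dir output directory (created if needed).
#' @param config a cost configuration list (`resources`, `unit_costs`), e.g.
#'   from [read_cost_config()]; defaults reproduce the trial costing.
#' @return The cost table, invisibly; side effect: `costs.csv` in `out_dir`.
#' @export
run_costs <- function(out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resources <- if (is.null(config)) default_resources() else config$resources
  unit_costs <- if (is.null(config)) default_unit_costs() else
    config$unit_costs
  costs <- cost_breakdown(resource_profiles(resources = resources),
                          unit_costs)
  readr::write_csv(costs, file.path(out_dir, "costs.csv"))
  invisible(costs)
}

#' Run the cost-effectiveness analyses and write their artifacts
#'
#' For each requested measure, runs [cea_analysis()] and writes a CEA table
#' CSV (cost-ordered rows with incremental columns and classification), a
#' frontier JSON (ordered frontier strategies, frontier ICERs and threshold
#' verdicts) and a plot-data CSV of (strategy, cost, accumulated,
#' classification) for frontier figures.
#'
#' @param out_dir output directory.
#' @param costs cost table (see [cea_inputs()]).
#' @param accumulated accumulated outcomes for all requested measures.
#' @param measures measures to analyse.
#' @param cet threshold range, NOK per QALY.
#' @param round_inputs see [cea_inputs()].
#' @return A named list of `"cea"` objects, invisibly.
#' @export
run_cea <- function(out_dir, costs, accumulated,
                    measures = c("masc", "smfq", "hrqol"),
                    cet = c(275000, 825000), round_inputs = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(accumulated) == 0) {
    stop("`accumulated` is empty: no outcomes to analyse.", call. = FALSE)
  }
  fits <- purrr::map(rlang::set_names(measures), function(m) {
    fit <- cea_analysis(cea_inputs(costs, accumulated, m, round_inputs),
                        measure = m, cet = cet)
    readr::write_csv(tidy(fit),
                     file.path(out_dir, paste0("cea_", m, ".csv")))
    frontier <- fit$frontier
    jsonlite::write_json(
      list(measure = fit$measure,
           frontier = frontier$strategy,
           frontier_icers = frontier$icer,
           cet = fit$cet,
           cet_verdicts = frontier$cet_verdict),
      file.path(out_dir, paste0("frontier_", m, ".json")),
      auto_unbox = FALSE, digits = NA, na = "null"
    )
    readr::write_csv(
      dplyr::select(fit$table, "strategy", "cost", "accumulated",
                    "classification"),
      file.path(out_dir, paste0("frontier_points_", m, ".csv"))
    )
    fit
  })
  invisible(fits)
}

#' Run the full pipeline end to end
#'
#' Orchestrates every stage: obtain trial records (simulate, read from file,
#' or skip in published-means mode), summarise them per arm and timepoint,
#' accumulate outcomes, cost the strategies, run the three cost-effectiveness
#' analyses and write all artifacts (records, targets, calibration report,
#' summary, accumulated outcomes, cost table, CEA tables, frontier JSONs and
#' plot data) to `out_dir`. All stages are deterministic given the seed.
#'
#' In published-means mode (`published_means = TRUE`) the simulation and
#' summarisation stages are bypassed and the published accumulated scores are
#' fed to the CEA directly — the arithmetic then reproduces the published
#' analysis tables.
#'
#' @param out_dir output directory.
#' @param seed random seed for the simulation stage.
#' @param records optional pre-loaded trial records (bypasses simulation).
#' @param records_file optional CSV of trial records (see
#'   [read_trial_records()]); at most one of `records`/`records_file` may be
#'   given.
#' @param published_means use the published arm-level results instead of
#'   individual records.
#' @param config optional cost configuration list.
#' @param measures measures to analyse.
#' @param cet threshold range, NOK per QALY.
#' @return Invisibly, a list with the cost table, summary, accumulated
#'   outcomes, CEA fits and (simulation mode) the calibration report.
#' @examples
#' out <- run_all(tempfile("cea"), seed = 42)
#' names(out$cea)
#' @export
run_all <- function(out_dir, seed = 1, records = NULL, records_file = NULL,
                    published_means = FALSE, config = NULL,
                    measures = c("masc", "smfq", "hrqol"),
                    cet = c(275000, 825000)) {
  if (!is.null(records) && !is.null(records_file)) {
    stop("Give at most one of `records` and `records_file`.", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  costs <- run_costs(out_dir, config)

  calibration <- NULL
  if (published_means) {
    summary <- published_summary()
    accumulated <- published_accumulated("printed")
  } else {
    if (!is.null(records_file)) {
      records <- read_trial_records(records_file)
    } else if (is.null(records)) {
      records <- simulate_trial(seed = seed)
      readr::write_csv(records, file.path(out_dir, "records.csv"))
      readr::write_csv(published_summary(),
                       file.path(out_dir, "targets.csv"))
      calibration <- validate_trial(records)
      jsonlite::write_json(
        list(ok = calibration$ok,
             means = calibration$means,
             correlations = calibration$correlations,
             sample_sizes = calibration$sample_sizes,
             rho_time_assumed = calibration$notes$rho_time,
             psd_adjustment = calibration$notes$psd_adjustment),
        file.path(out_dir, "calibration.json"),
        auto_unbox = TRUE, digits = NA, na = "null"
      )
      txt <- utils::capture.output(print(calibration))
      writeLines(txt, file.path(out_dir, "calibration.txt"))
    }
    summary <- timepoint_summary(records)
    accumulated <- accumulate_outcomes(summary)
  }
  readr::write_csv(summary, file.path(out_dir, "timepoint_summary.csv"))
  readr::write_csv(accumulated, file.path(out_dir, "accumulated.csv"))
  fits <- run_cea(out_dir, costs, accumulated, measures, cet)
  invisible(list(costs = costs, summary = summary,
                 accumulated = accumulated, cea = fits,
                 calibration = calibration))
}
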