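#' Trapezoidal accumulation of three repeated measurements
#'
#' Measurements were taken at inclusion (T1, week 0), week 12 (T2) and week 62
#' (T3). The accumulated score over the 62-week window is the area under the
#' piecewise-linear trajectory through the three timepoint values, expressed
#' in score-years with a 52-week year:
#' `(m1 + m2)/2 * 12/52 + (m2 + m3)/2 * 50/52`.
#' Applied to HRQoL utilities this is the QALYs accrued over the window.
#'
#' @param m1,m2,m3 numeric vectors: the value at each timepoint (typically the
#'   available-case arm mean). Missing values are an error — aggregate to
#'   available-case means first.
#' @param interval_weeks lengths of the T1–T2 and T2–T3 intervals in weeks.
#' @param weeks_per_year year denominator; 52 by convention here.
#' @return Accumulated score in score-years (QALYs for HRQoL).
#' @examples
#' trapezoid_accumulate(73.25, 61.78, 57.61) # accumulated MASC, approx 72.98
#' trapezoid_accumulate(1, 1, 1)             # perfect health: 62/52 QALYs
#' @export
trapezoid_accumulate <- function(m1, m2, m3,
                                 interval_weeks = c(12, 50),
                                 weeks_per_year = 52) {
  if (length(interval_weeks) != 2 || any(interval_weeks < 0)) {
    stop("`interval_weeks` must be two non-negative interval lengths.",
         call. = FALSE)
  }
  vals <- cbind(m1, m2, m3)
  if (any(is.na(vals)) || any(!is.finite(vals))) {
    stop("Timepoint values must be finite and non-missing; compute ",
         "available-case means before accumulating.", call. = FALSE)
  }
  w <- interval_weeks / weeks_per_year
  (m1 + m2) / 2 * w[1] + (m2 + m3) / 2 * w[2]
}

measure_columns <- function(records) {
  wanted <- paste0(rep(c("masc", "smfq", "hrqol"), each = 3), "_t", 1:3)
  missing <- setdiff(wanted, names(records))
  if (length(missing) > 0) {
    stop("Trial records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wanted
}

records_long <- function(records) {
  measure_columns(records)
  long <- tidyr::pivot_longer(
    records,
    cols = dplyr::matches("^(masc|smfq|hrqol)_t[123]$"),
    names_to = c("measure", "timepoint"),
    names_pattern = "^(masc|smfq|hrqol)_t([123])$",
    values_to = "value"
  )
  dplyr::mutate(long, timepoint = as.integer(.data$timepoint))
}

#' Per-arm, per-timepoint summary of trial records
#'
#' Available-case summaries: children missing a measure at a timepoint are
#' excluded from that timepoint only. The standard deviation of a single
#' observation is reported as missing by default.
#'
#' @param records a tibble of individual trial records, one row per child,
#'   with columns `id`, `strategy` and `masc_t1` … `hrqol_t3`
#'   (see [simulate_trial()] / [read_trial_records()] for the schema).
#' @param measures which measures to summarise (default all three).
#' @param sd_single value reported as the SD of a single observation: `NA`
#'   (default) or `0`.
#' @return A tibble with columns `strategy`, `measure`, `timepoint` (1–3),
#'   `n`, `mean`, `sd`.
#' @examples
#' records <- simulate_trial(seed = 1)
#' timepoint_summary(records)
#' @export
timepoint_summary <- function(records, measures = c("masc", "smfq", "hrqol"),
                              sd_single = NA_real_) {
  measures <- measure_specs(measures)$measure
  long <- dplyr::filter(records_long(records), .data$measure %in% measures)
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$strategy, .data$measure, .data$timepoint),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  empty <- out$n == 0
  if (any(empty)) {
    bad <- out[empty, ]
    stop("No non-missing values for ",
         paste(sprintf("%s/%s/T%d", bad$strategy, bad$measure, bad$timepoint),
               collapse = "; "),
         call. = FALSE)
  }
  out$sd[out$n == 1] <- sd_single
  dplyr::arrange(out, .data$strategy, .data$measure, .data$timepoint)
}

#' Accumulated outcome per arm and measure
#'
#' Applies [trapezoid_accumulate()] to the per-timepoint arm means, giving
#' the accumulated score over the observation window (QALYs for `hrqol`).
#'
#' @param summary a per-timepoint summary as returned by [timepoint_summary()]
#'   (columns `strategy`, `measure`, `timepoint`, `mean`), or raw trial
#'   records, which are summarised first.
#' @inheritParams trapezoid_accumulate
#' @return A tibble with columns `strategy`, `measure`, `accumulated`.
#' @examples
#' records <- simulate_trial(seed = 1)
#' accumulate_outcomes(records)
#' @export
accumulate_outcomes <- function(summary,
                                interval_weeks = c(12, 50),
                                weeks_per_year = 52) {
  if (!all(c("measure", "timepoint", "mean") %in% names(summary))) {
    summary <- timepoint_summary(summary)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(summary, "strategy", "measure", "timepoint", "mean"),
    names_from = "timepoint", values_from = "mean", names_prefix = "m"
  )
  if (!all(c("m1", "m2", "m3") %in% names(wide)) || anyNA(wide)) {
    stop("Accumulation needs a mean at each of the three timepoints for ",
         "every strategy/measure.", call. = FALSE)
  }
  out <- dplyr::mutate(
    wide,
    accumulated = trapezoid_accumulate(.data$m1, .data$m2, .data$m3,
                                       interval_weeks, weeks_per_year)
  )
  dplyr::select(out, "strategy", "measure", "accumulated")
}

#' Baseline (T1) correlations among the outcome measures
#'
#' Pairwise-complete Pearson correlations between MASC, SMFQ and HRQoL at
#' inclusion, pooled over strategies, with the test p-value and the number of
#' complete pairs.
#'
#' @inheritParams timepoint_summary
#' @return A tibble with columns `measure1`, `measure2`, `r`, `p`, `n`.
#' @examples
#' records <- simulate_trial(seed = 1)
#' t1_correlations(records)
#' @export
t1_correlations <- function(records) {
  cols <- c(masc = "masc_t1", smfq = "smfq_t1", hrqol = "hrqol_t1")
  measure_columns(records)
  pairs <- utils::combn(names(cols), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    x <- records[[cols[[p[1]]]]]
    y <- records[[cols[[p[2]]]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      stop("Fewer than 3 complete pairs for ", p[1], " vs ", p[2],
           " at T1.", call. = FALSE)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(measure1 = p[1], measure2 = p[2],
                   r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
}
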