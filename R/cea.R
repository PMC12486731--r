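#' Orient an accumulated outcome as a health effect
#'
#' ICERs are expressed in cost per unit of *improvement*. For symptom scores
#' (benefit direction `"decrease"`) improvement is a reduction, so the
#' oriented effect is the negated accumulated score; for utilities/QALYs
#' (`"increase"`) the accumulated value is the effect as-is. Larger oriented
#' effect always means better health.
#'
#' @param accumulated numeric vector of accumulated scores.
#' @param measure a single measure name (see [measure_specs()]).
#' @return Numeric vector of oriented effects.
#' @examples
#' orient_effect(72.98, "masc")  # -72.98
#' orient_effect(0.938, "hrqol") # 0.938
#' @export
orient_effect <- function(accumulated, measure) {
  spec <- measure_specs(measure)
  if (nrow(spec) != 1) stop("`measure` must be a single measure name.",
                            call. = FALSE)
  if (spec$benefit_direction == "decrease") -accumulated else accumulated
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `(cost_comparator - cost_reference) / (effect_comparator - effect_reference)`
#' with effects in oriented improvement units. A negative ICER signals worse
#' health at extra cost; equal effects yield `Inf` ("undefined": no finite
#' price per unit of improvement), not an error.
#'
#' @param reference,comparator one-row data frames with columns `strategy`,
#'   `cost` and `effect` (oriented; see [orient_effect()]). The comparator is
#'   the costlier strategy.
#' @return The ICER in NOK per unit of improvement.
#' @examples
#' icer(
#'   reference  = data.frame(strategy = "SLN", cost = 5124, effect = -72.98),
#'   comparator = data.frame(strategy = "SLF", cost = 6862, effect = -66.79)
#' )
#' @export
icer <- function(reference, comparator) {
  for (x in list(reference, comparator)) {
    if (!is.data.frame(x) || nrow(x) != 1 ||
        !all(c("strategy", "cost", "effect") %in% names(x))) {
      stop("`reference` and `comparator` must be one-row data frames with ",
           "columns strategy, cost, effect.", call. = FALSE)
    }
  }
  if (identical(reference$strategy, comparator$strategy)) {
    stop("Cannot compare a strategy with itself.", call. = FALSE)
  }
  if (comparator$cost < reference$cost) {
    stop("`comparator` must be the costlier strategy (cost-ordered ",
         "comparison).", call. = FALSE)
  }
  delta_c <- comparator$cost - reference$cost
  delta_e <- comparator$effect - reference$effect
  if (delta_e == 0) {
    return(Inf)
  }
  delta_c / delta_e
}

# adjacent ICER sequence along cost-ordered strategies; Inf where the effect
# does not change
adjacent_icers <- function(cost, effect) {
  dc <- diff(cost)
  de <- diff(effect)
  ifelse(de == 0, Inf, dc / de)
}

#' Cost-effectiveness analysis of a set of strategies
#'
#' Orders strategies by cost, computes adjacent incremental costs, effects and
#' ICERs, classifies every strategy as on the frontier, dominated, or extended
#' dominated, and computes the frontier ICERs:
#'
#' 1. sort by cost ascending (ties: better effect first; exact cost/effect
#'    ties collapse to one frontier representative, the duplicates being
#'    weakly dominated);
#' 2. *strong (and weak) dominance*: a strategy is dominated when some other
#'    strategy has no higher cost and no worse effect, with at least one
#'    strict inequality;
#' 3. *extended dominance*: among the survivors, adjacent ICERs are computed
#'    and any strategy whose incoming ICER is at least its outgoing ICER is
#'    removed, repeating until the ICER sequence is strictly increasing;
#' 4. the survivors form the cost-effectiveness frontier.
#'
#' @param inputs a data frame with one row per strategy and columns
#'   `strategy`, `cost` (per child, NOK) and `accumulated` (the accumulated
#'   outcome from [accumulate_outcomes()]).
#' @param measure the outcome measure name; fixes the benefit orientation and
#'   whether a QALY threshold applies.
#' @param cet cost-effectiveness threshold range in NOK per QALY (lower,
#'   upper); used only when `measure = "hrqol"`.
#' @return An object of class `"cea"`: a list with
#'   \describe{
#'     \item{table}{one row per strategy in cost order: `cost`, `incr_cost`,
#'       `accumulated`, `incr_effect` (oriented improvement vs the
#'       next-cheapest strategy), `icer`, `classification`
#'       (`"frontier"`, `"dominated"`, `"extended_dominated"`), and the
#'       frontier-only columns `frontier_incr_cost`, `frontier_incr_effect`,
#'       `frontier_icer`.}
#'     \item{frontier}{the frontier subset with its ICERs and, for QALYs,
#'       threshold verdicts from [cet_verdict()].}
#'     \item{measure, cet}{the analysis settings.}
#'   }
#' @examples
#' inputs <- dplyr::inner_join(
#'   dplyr::transmute(cost_breakdown(), strategy = code,
#'                    cost = round(per_child)),
#'   dplyr::filter(published_accumulated(), measure == "masc"),
#'   by = "strategy"
#' )
#' fit <- cea_analysis(inputs, measure = "masc")
#' fit$frontier$strategy # SLN, SLF, LLF
#' @export
cea_analysis <- function(inputs, measure, cet = c(275000, 825000)) {
  if (!is.data.frame(inputs) || nrow(inputs) < 1) {
    stop("`inputs` must be a data frame with at least one strategy.",
         call. = FALSE)
  }
  needed <- c("strategy", "cost", "accumulated")
  if (!all(needed %in% names(inputs))) {
    stop("`inputs` must have columns strategy, cost, accumulated.",
         call. = FALSE)
  }
  if (anyDuplicated(inputs$strategy) > 0) {
    stop("Duplicate strategy codes in `inputs`.", call. = FALSE)
  }
  if (any(inputs$cost < 0)) {
    stop("Costs must be non-negative.", call. = FALSE)
  }

  tab <- tibble::as_tibble(inputs[needed])
  tab$effect <- orient_effect(tab$accumulated, measure)
  tab <- dplyr::arrange(tab, .data$cost, dplyr::desc(.data$effect),
                        .data$strategy)

  n <- nrow(tab)
  class_ <- rep(NA_character_, n)

  # exact (cost, effect) ties: keep the first as representative
  dup <- duplicated(tab[c("cost", "effect")])
  class_[dup] <- "dominated"

  # weak dominance sweep
  for (i in seq_len(n)) {
    if (!is.na(class_[i])) next
    others <- setdiff(seq_len(n), i)
    dominated <- any(
      tab$cost[others] <= tab$cost[i] & tab$effect[others] >= tab$effect[i] &
        (tab$cost[others] < tab$cost[i] | tab$effect[others] > tab$effect[i])
    )
    if (dominated) class_[i] <- "dominated"
  }

  # extended dominance: prune until adjacent frontier ICERs strictly increase
  survivors <- which(is.na(class_))
  repeat {
    if (length(survivors) < 3) break
    ic <- adjacent_icers(tab$cost[survivors], tab$effect[survivors])
    kink <- which(ic[-length(ic)] >= ic[-1])
    if (length(kink) == 0) break
    drop <- survivors[kink[1] + 1]
    class_[drop] <- "extended_dominated"
    survivors <- setdiff(survivors, drop)
  }
  class_[is.na(class_)] <- "frontier"
  tab$classification <- class_

  # adjacent incremental columns for the full cost-ordered table
  tab$incr_cost <- c(NA, diff(tab$cost))
  tab$incr_effect <- c(NA, diff(tab$effect))
  tab$icer <- c(NA, adjacent_icers(tab$cost, tab$effect))

  # frontier increments
  idx <- which(tab$classification == "frontier")
  tab$frontier_incr_cost <- NA_real_
  tab$frontier_incr_effect <- NA_real_
  tab$frontier_icer <- NA_real_
  if (length(idx) > 1) {
    tab$frontier_incr_cost[idx[-1]] <- diff(tab$cost[idx])
    tab$frontier_incr_effect[idx[-1]] <- diff(tab$effect[idx])
    tab$frontier_icer[idx[-1]] <- adjacent_icers(tab$cost[idx],
                                                 tab$effect[idx])
  }

  frontier <- dplyr::select(
    tab[idx, ],
    "strategy", "cost", "accumulated", "effect",
    icer = "frontier_icer"
  )
  if (identical(measure_specs(measure)$measure, "hrqol")) {
    frontier$cet_verdict <- cet_verdict(frontier$icer, cet)
  } else {
    frontier$cet_verdict <- NA_character_
    attr(frontier, "cet_note") <-
      "No cost-effectiveness threshold is defined for symptom-score outcomes."
  }

  out <- list(
    table = dplyr::select(
      tab, "strategy", "cost", "incr_cost", "accumulated", "incr_effect",
      "icer", "classification", "frontier_incr_cost", "frontier_incr_effect",
      "frontier_icer"
    ),
    frontier = frontier,
    measure = measure_specs(measure)$measure,
    cet = cet
  )
  class(out) <- "cea"
  out
}

#' Compare frontier ICERs against a willingness-to-pay threshold range
#'
#' Norwegian priority-setting guidance uses a severity-dependent threshold
#' range of NOK 275,000 to 825,000 per QALY gained. Each ICER is labelled
#' `"below_lower_bound"` (at or under the lower bound: cost-effective even for
#' the least severe conditions), `"within_range"`, or `"above_upper_bound"`.
#' A threshold is defined only for QALYs; symptom-score ICERs have no
#' threshold and should not be passed here.
#'
#' @param icers numeric vector of ICERs in NOK per QALY (NA allowed for the
#'   cheapest frontier member, which has no comparator).
#' @param cet numeric length-2 threshold range (lower, upper), NOK per QALY.
#' @return Character vector of verdicts, `NA` where `icers` is `NA`.
#' @examples
#' cet_verdict(c(NA, 96743, 500000, 900000))
#' @export
cet_verdict <- function(icers, cet = c(275000, 825000)) {
  if (length(cet) != 2 || cet[1] > cet[2]) {
    stop("`cet` must be an increasing (lower, upper) threshold pair.",
         call. = FALSE)
  }
  dplyr::case_when(
    is.na(icers) ~ NA_character_,
    icers <= cet[1] ~ "below_lower_bound",
    icers <= cet[2] ~ "within_range",
    TRUE ~ "above_upper_bound"
  )
}

#' @export
print.cea <- function(x, ...) {
  cat("Cost-effectiveness analysis (", x$measure, ")\n", sep = "")
  cat("Frontier: ", paste(x$frontier$strategy, collapse = " -> "), "\n\n",
      sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Tidy a cost-effectiveness analysis
#'
#' @param x a `"cea"` object from [cea_analysis()].
#' @param ... unused.
#' @return The full cost-ordered CEA table as a tibble, one row per strategy,
#'   with a `measure` column prepended.
#' @method tidy cea
#' @export
tidy.cea <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(measure = x$measure), x$table)
}

#' One-row summary of a cost-effectiveness analysis
#'
#' @inheritParams tidy.cea
#' @return A one-row tibble: measure, numbers of strategies by classification,
#'   the cheapest frontier strategy and the largest frontier ICER.
#' @method glance cea
#' @export
glance.cea <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    n_strategies = nrow(x$table),
    n_frontier = sum(x$table$classification == "frontier"),
    n_dominated = sum(x$table$classification == "dominated"),
    n_extended_dominated =
      sum(x$table$classification == "extended_dominated"),
    cheapest = x$frontier$strategy[1],
    max_frontier_icer = suppressWarnings(max(x$frontier$icer, na.rm = TRUE))
  )
}

#' Plot the cost-effectiveness frontier
#'
#' Strategies are drawn in the (accumulated outcome, cost-per-child) plane,
#' coloured by classification, with the frontier members connected. For
#' symptom scores the x-axis decreases to the right so that better health is
#' always rightward.
#'
#' @param object a `"cea"` object.
#' @param label logical; label points with the strategy codes.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cea
#' @export
autoplot.cea <- function(object, label = TRUE, ...) {
  tab <- object$table
  frontier <- tab[tab$classification == "frontier", ]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$accumulated,
                                         y = .data$cost)) +
    ggplot2::geom_line(data = frontier, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$classification),
                        size = 2.5) +
    ggplot2::labs(
      x = paste0("Accumulated ", toupper(object$measure),
                 if (object$measure == "hrqol") " (QALYs)" else ""),
      y = "Cost per child (NOK)", colour = NULL,
      title = paste0("Cost-effectiveness frontier (",
                     toupper(object$measure), ")")
    ) +
    ggplot2::theme_minimal()
  if (measure_specs(object$measure)$benefit_direction == "decrease") {
    p <- p + ggplot2::scale_x_reverse()
  }
  if (label) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                                vjust = -0.8, size = 3)
  }
  p
}

#' @rdname autoplot.cea
#' @param x a `"cea"` object.
#' @param y unused.
#' @export
plot.cea <- function(x, y, ...) print(autoplot.cea(x, ...))
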