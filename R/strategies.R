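#' The eight delivery strategies as a 2 x 2 x 2 factor grid
#'
#' The prevention programme was optimised over three binary delivery factors:
#' delivery format (`"long"`: 16 in-person child sessions, vs `"hybrid"`:
#' 8 in-person + 8 web-based sessions), parental involvement (`"high"`:
#' 5 parent group sessions, vs `"low"`: a psychoeducational brochure), and a
#' measurement feedback system (`"feedback"` vs `"none"`). Each of the eight
#' combinations is labelled by a three-letter code: first letter `S` (short /
#' hybrid) or `L` (long), second `L` (low) or `H` (high parental involvement),
#' third `N` (no feedback) or `F` (feedback). So `"SLN"` is
#' hybrid / brochure / no feedback and `"LHF"` is long / parent sessions /
#' feedback.
#'
#' @return A tibble with one row per strategy and columns `code`, `delivery`,
#'   `parental`, `feedback`, plus the implied session counts `child_sessions`
#'   (8 in-person for hybrid, 16 for long; web-based sessions carry no group
#'   leader contact time) and `parent_sessions` (5 or 0).
#' @examples
#' strategy_grid()
#' @export
strategy_grid <- function() {
  grid <- tidyr::expand_grid(
    delivery = c("hybrid", "long"),
    parental = c("low", "high"),
    feedback = c("none", "feedback")
  )
  grid <- dplyr::mutate(
    grid,
    code = paste0(
      ifelse(.data$delivery == "hybrid", "S", "L"),
      ifelse(.data$parental == "low", "L", "H"),
      ifelse(.data$feedback == "none", "N", "F")
    ),
    child_sessions = ifelse(.data$delivery == "hybrid", 8L, 16L),
    parent_sessions = ifelse(.data$parental == "high", 5L, 0L)
  )
  dplyr::select(
    grid, "code", "delivery", "parental", "feedback",
    "child_sessions", "parent_sessions"
  )
}

#' Decode three-letter strategy codes into the factor triple
#'
#' @param code character vector of strategy codes such as `"SLN"` or `"LHF"`.
#' @return A tibble with one row per input code, joined from [strategy_grid()].
#' @examples
#' strategy_from_code(c("SLN", "LHF"))
#' @export
strategy_from_code <- function(code) {
  grid <- strategy_grid()
  bad <- setdiff(unique(code), grid$code)
  if (length(bad) > 0) {
    stop("Unknown strategy code(s): ", paste(bad, collapse = ", "),
         ". Valid codes: ", paste(grid$code, collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(tibble::tibble(code = code), grid, by = "code")
}

# strategy codes in the canonical ascending-cost order of the costing model
strategy_cost_order <- c("SLN", "SLF", "SHN", "LLN", "SHF", "LLF", "LHN", "LHF")
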