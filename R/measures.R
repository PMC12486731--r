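#' Outcome measure definitions
#'
#' The three health outcomes tracked by the trial:
#' * `masc` — Multidimensional Anxiety Scale for Children, integer sum score
#'   0–117, lower is better;
#' * `smfq` — Short Mood and Feelings Questionnaire, integer sum score 0–26,
#'   lower is better;
#' * `hrqol` — health-related quality of life utility on \[0, 1\], higher is
#'   better. Accumulating `hrqol` over time yields QALYs.
#'
#' @param name optionally, a character vector of measure names to select
#'   (case-insensitive).
#' @return A tibble with columns `measure`, `scale_min`, `scale_max`,
#'   `benefit_direction` (`"decrease"` or `"increase"`), `integer_valued`.
#' @examples
#' measure_specs()
#' measure_specs("hrqol")
#' @export
measure_specs <- function(name = NULL) {
  specs <- tibble::tribble(
    ~measure, ~scale_min, ~scale_max, ~benefit_direction, ~integer_valued,
    "masc",   0,          117,        "decrease",          TRUE,
    "smfq",   0,          26,         "decrease",          TRUE,
    "hrqol",  0,          1,          "increase",          FALSE
  )
  if (is.null(name)) {
    return(specs)
  }
  name <- tolower(name)
  bad <- setdiff(name, specs$measure)
  if (length(bad) > 0) {
    stop("Unknown measure(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  specs[match(name, specs$measure), ]
}

#' HRQoL utility mapping hook
#'
#' The trial derived HRQoL utilities from ten Kidscreen items through a
#' published scoring algorithm that is consumed, not re-estimated, by this
#' package. Utilities are therefore taken as already computed; this hook
#' exists so that an alternative instrument-to-utility mapping can be plugged
#' into the pipeline. The default is the identity pass-through.
#'
#' @param hrqol numeric vector of utilities on \[0, 1\].
#' @param mapping a function applied to `hrqol`; defaults to [identity()].
#' @return The mapped utilities.
#' @export
map_hrqol_utility <- function(hrqol, mapping = identity) {
  out <- mapping(hrqol)
  if (any(stats::na.omit(out) < 0 | stats::na.omit(out) > 1)) {
    stop("Mapped utilities must lie in [0, 1].", call. = FALSE)
  }
  out
}
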