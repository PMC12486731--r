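# Shared fixtures and independent oracles.

# CEA inputs as displayed in the published tables: integer-rounded per-child
# costs joined with the published accumulated outcomes.
published_inputs <- function(measure) {
  cea_inputs(cost_breakdown(), published_accumulated(), measure)
}

# Published per-strategy accumulated values in canonical cost order.
published_acc_vector <- function(measure) {
  acc <- published_accumulated()
  acc <- acc[acc$measure == measure, ]
  acc$accumulated[match(ceafrontier:::strategy_cost_order, acc$strategy)]
}

# Brute-force frontier oracle, independent of the package's iterative
# ICER-pruning algorithm: a strategy is efficient iff no other strategy, and
# no convex blend of two other strategies, attains at least its effect for
# strictly less cost (or more effect at no more cost). For n <= 8 the full
# pair enumeration is exact.
oracle_frontier <- function(cost, effect) {
  n <- length(cost)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (cost[j] <= cost[i] && effect[j] >= effect[i] &&
          (cost[j] < cost[i] || effect[j] > effect[i])) {
        keep[i] <- FALSE
      }
    }
    if (!keep[i]) next
    for (j in seq_len(n - 1)) {
      for (k in seq.int(j + 1, n)) {
        if (j == i || k == i) next
        if (effect[j] == effect[k]) next
        lam <- (effect[i] - effect[k]) / (effect[j] - effect[k])
        if (lam >= 0 && lam <= 1) {
          mix_cost <- lam * cost[j] + (1 - lam) * cost[k]
          if (mix_cost < cost[i]) keep[i] <- FALSE
        }
      }
    }
  }
  which(keep)
}

# Random CEA instance with continuous costs/effects (ties have probability 0).
random_instance <- function(n) {
  tibble::tibble(
    strategy = paste0("S", seq_len(n)),
    cost = stats::runif(n, 1000, 15000),
    accumulated = stats::runif(n)
  )
}

# Small benign simulation targets: two arms, mid-scale means far from the
# bounds so clipping is negligible.
tiny_targets <- function(n = c(20, 15, 10), strategies = c("SLN", "LLN")) {
  base <- tibble::tribble(
    ~measure, ~mean1, ~mean2, ~mean3, ~sd,
    "masc",   60,     55,     50,     10,
    "smfq",   13,     11,     10,     4,
    "hrqol",  0.70,   0.72,   0.75,   0.08
  )
  grid <- tidyr::expand_grid(strategy = strategies,
                             measure = base$measure, timepoint = 1:3)
  grid <- dplyr::left_join(grid, base, by = "measure")
  dplyr::transmute(
    grid,
    strategy = .data$strategy, measure = .data$measure,
    timepoint = .data$timepoint,
    n = n[.data$timepoint],
    mean = dplyr::case_when(.data$timepoint == 1 ~ .data$mean1,
                            .data$timepoint == 2 ~ .data$mean2,
                            TRUE ~ .data$mean3),
    sd = .data$sd
  )
}

# Hand-built three-child record set for summary arithmetic.
hand_records <- function() {
  tibble::tibble(
    child_id = c("a", "b", "c"),
    strategy = "SLN",
    wave = 2L, sex = "girl", age = 10,
    masc_t1 = c(10, 12, 14), masc_t2 = c(9, 11, NA), masc_t3 = c(8, NA, NA),
    smfq_t1 = c(5, 6, 7), smfq_t2 = c(4, 5, NA), smfq_t3 = c(3, NA, NA),
    hrqol_t1 = c(0.7, 0.8, 0.9), hrqol_t2 = c(0.7, 0.8, NA),
    hrqol_t3 = c(0.75, NA, NA)
  )
}
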