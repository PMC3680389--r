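default_blocks <- c("1-10", "11-15", "16-20", "11-20", "21-30")

parse_block <- function(label) {
  parts <- suppressWarnings(as.integer(strsplit(label, "-", fixed = TRUE)[[1]]))
  if (length(parts) != 2 || anyNA(parts) || parts[1] > parts[2]) {
    abort(sprintf("malformed block label `%s`; expected \"first-last\"", label))
  }
  seq.int(parts[1], parts[2])
}

rounds_table <- function(x) {
  if (inherits(x, "norm_sim")) return(x$rounds)
  if (is.data.frame(x)) return(x)
  abort("expected a norm_sim object or a rounds data frame")
}

# group-level means first (one value per treatment x replication x group),
# then averaged across groups: the group is the independent unit
two_stage_mean <- function(rounds, var, blocks) {
  purrr::map_dfr(blocks, function(b) {
    in_block <- dplyr::filter(rounds, .data$round %in% parse_block(b))
    if (nrow(in_block) == 0) abort(sprintf("block %s contains no rounds", b))
    in_block |>
      dplyr::group_by(.data$treatment, .data$replication, .data$group) |>
      dplyr::summarise(m = mean(.data[[var]]), .groups = "drop") |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(m = mean(.data$m), .groups = "drop") |>
      dplyr::mutate(block = b, .after = "treatment")
  })
}

#' Block-level mean contributions
#'
#' Mean contribution per treatment and round block, computed group-first:
#' each (replication, group) contributes one mean, and those independent
#' group means are then averaged. Applied to the fixture table of reported
#' human block means, it simply returns the requested cells.
#'
#' @param x A `norm_sim` object, an agent-round data frame with columns
#'   `treatment`, `replication`, `group`, `round`, `contribution`, or a
#'   fixture table from [human_baseline()].
#' @param blocks Character vector of `"first-last"` round-block labels.
#' @return A tibble with columns `treatment`, `block`, `mean_contribution`.
#' @examples
#' block_means(human_baseline(), blocks = "16-20")
#' @export
block_means <- function(x, blocks = default_blocks) {
  if (inherits(x, "fixture_table")) {
    missing <- setdiff(blocks, unique(x$block))
    if (length(missing) > 0) {
      abort(sprintf("fixture table has no block(s) %s", paste(missing, collapse = ", ")))
    }
    out <- dplyr::filter(x, .data$block %in% blocks)
    return(dplyr::select(out, "treatment", "block", "mean_contribution"))
  }
  out <- two_stage_mean(rounds_table(x), "contribution", blocks)
  dplyr::rename(out, mean_contribution = "m")
}

#' Net earnings per member per round, by treatment and block
#'
#' Mean final payoff (after punishment costs on both sides) per member per
#' round, aggregated group-first like [block_means()]. This is the quantity
#' behind statements such as "net earnings are higher under sanctions than
#' under bare punishment".
#'
#' @inheritParams block_means
#' @return A tibble with columns `treatment`, `block`, `mean_earnings`.
#' @export
earnings_summary <- function(x, blocks = default_blocks) {
  out <- two_stage_mean(rounds_table(x), "final_payoff", blocks)
  dplyr::rename(out, mean_earnings = "m")
}

acts_scope <- function(x, rounds) {
  if (!inherits(x, "norm_sim")) {
    abort("punishment frequency/intensity need a norm_sim object (per-act records)")
  }
  if (length(rounds) == 0) abort("empty round scope")
  dplyr::filter(x$acts, .data$round %in% rounds)
}

#' Punishment frequency
#'
#' The share of sender-to-target punishment opportunities actually used:
#' the number of allocations with positive points divided by the number of
#' ordered sender-target pairs in the scope (`group_size * (group_size - 1)`
#' per group-round), regardless of how many points each act carried.
#' Treatments without the punishment instrument simply score 0.
#'
#' @param x A `norm_sim` object.
#' @param rounds Integer vector of rounds in scope; defaults to the
#'   configured instrument rounds.
#' @return A tibble with columns `treatment`, `n_acts`, `n_opportunities`,
#'   `frequency`.
#' @export
punishment_frequency <- function(x, rounds = NULL) {
  rounds <- rounds %||% x$config$instrument_rounds
  acts <- acts_scope(x, rounds)
  cfg <- x$config
  n <- cfg$game$group_size
  n_opp <- cfg$replications * cfg$n_groups * length(rounds) * n * (n - 1)
  if (n_opp == 0) abort("scope contains no punishment opportunities")
  acts |>
    dplyr::count(.data$treatment, name = "n_acts", .drop = FALSE) |>
    dplyr::mutate(n_opportunities = n_opp,
                  frequency = .data$n_acts / .data$n_opportunities)
}

#' Punishment intensity
#'
#' The mean number of points per punishing act, excluding all zero-point
#' instances. When a treatment has no punishing acts in scope, its
#' intensity is undefined and reported as `NA` (never as 0).
#'
#' @inheritParams punishment_frequency
#' @return A tibble with columns `treatment`, `n_acts`, `intensity`
#'   (`NA` where no acts occurred).
#' @export
punishment_intensity <- function(x, rounds = NULL) {
  rounds <- rounds %||% x$config$instrument_rounds
  acts <- acts_scope(x, rounds)
  acts |>
    dplyr::group_by(.data$treatment, .drop = FALSE) |>
    dplyr::summarise(n_acts = dplyr::n(),
                     intensity = mean(.data$points), .groups = "drop") |>
    dplyr::mutate(intensity = ifelse(.data$n_acts == 0, NA_real_, .data$intensity))
}

#' Percent excess of one mean over another
#'
#' `round(100 * (a - b) / b)` to the nearest integer percent: by how many
#' percent `a` exceeds the base `b`. Vectorized; `b` must be positive.
#'
#' @param a,b Numeric values (e.g. block mean contributions); `b` is the
#'   base of the comparison.
#' @return Integer percent(s).
#' @examples
#' percent_excess(14.46, 10.65)  # 36
#' percent_excess(9.08, 3.75)   # 142
#' @export
percent_excess <- function(a, b) {
  if (any(is.na(b)) || any(b <= 0)) abort("`b` must be positive")
  as.integer(round(100 * (a - b) / b))
}

#' Per-replication treatment means and punishment frequencies
#'
#' Replication-level aggregates for group-level inference: each replication
#' of each treatment contributes one value (its groups averaged first), so
#' the rows of the result are independent draws suitable for the
#' nonparametric test battery.
#'
#' @param x A `norm_sim` object.
#' @param rounds Integer vector of rounds in scope; defaults to the
#'   configured instrument rounds.
#' @param var Column of the agent-round panel to average (for
#'   `replication_means`).
#' @return A tibble with one row per treatment and replication:
#'   `mean_value` for `replication_means()`, or `n_acts` and `frequency`
#'   for `replication_frequencies()`.
#' @export
replication_means <- function(x, rounds = NULL, var = "contribution") {
  rounds <- rounds %||% x$config$instrument_rounds
  if (length(rounds) == 0) abort("empty round scope")
  rounds_table(x) |>
    dplyr::filter(.data$round %in% rounds) |>
    dplyr::group_by(.data$treatment, .data$replication, .data$group) |>
    dplyr::summarise(m = mean(.data[[var]]), .groups = "drop") |>
    dplyr::group_by(.data$treatment, .data$replication) |>
    dplyr::summarise(mean_value = mean(.data$m), .groups = "drop")
}

#' @rdname replication_means
#' @export
replication_frequencies <- function(x, rounds = NULL) {
  rounds <- rounds %||% x$config$instrument_rounds
  acts <- acts_scope(x, rounds)
  cfg <- x$config
  n <- cfg$game$group_size
  opp <- cfg$n_groups * length(rounds) * n * (n - 1)
  acts |>
    dplyr::count(.data$treatment, .data$replication, name = "n_acts") |>
    tidyr::complete(.data$treatment, replication = seq_len(cfg$replications),
                    fill = list(n_acts = 0L)) |>
    dplyr::mutate(frequency = .data$n_acts / opp)
}
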