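round_series <- function(x, var) {
  x$rounds |>
    dplyr::group_by(.data$treatment, .data$replication, .data$group, .data$round) |>
    dplyr::summarise(v = mean(.data[[var]]), .groups = "drop") |>
    dplyr::group_by(.data$treatment, .data$round) |>
    dplyr::summarise(v = mean(.data$v), .groups = "drop")
}

#' Plot a simulation result
#'
#' Round-by-round treatment curves, in the style of the standard figures of
#' this design: mean contribution (`"cooperation"`), punishment frequency
#' over sender-target opportunities (`"punishment_frequency"`), or the mean
#' norm-salience trace (`"salience"`). Dashed verticals mark the
#' instrumented block.
#'
#' @param object A `norm_sim` object.
#' @param metric One of `"cooperation"`, `"punishment_frequency"`,
#'   `"salience"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sim <- run_experiment(simulation_config(n_groups = 2, replications = 2, seed = 5))
#' autoplot(sim)
#' @method autoplot norm_sim
#' @export
autoplot.norm_sim <- function(object,
                              metric = c("cooperation", "punishment_frequency", "salience"),
                              ...) {
  metric <- match.arg(metric)
  cfg <- object$config
  if (metric == "punishment_frequency") {
    n <- cfg$game$group_size
    per_round_opp <- cfg$replications * cfg$n_groups * n * (n - 1)
    dat <- object$acts |>
      dplyr::count(.data$treatment, .data$round, name = "n_acts", .drop = FALSE) |>
      tidyr::complete(.data$treatment, round = seq_len(cfg$game$rounds),
                      fill = list(n_acts = 0L)) |>
      dplyr::mutate(v = .data$n_acts / per_round_opp)
    ylab <- "punishment frequency"
  } else {
    var <- switch(metric, cooperation = "contribution", salience = "salience")
    dat <- round_series(object, var)
    ylab <- switch(metric, cooperation = "mean contribution (ECU)",
                   salience = "mean norm salience")
  }
  marks <- if (length(cfg$instrument_rounds) > 0) {
    c(min(cfg$instrument_rounds) - 0.5, max(cfg$instrument_rounds) + 0.5)
  } else {
    numeric(0)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$round, y = .data$v,
                                    colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = marks, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "round", y = ylab, colour = "treatment") +
    ggplot2::theme_minimal()
}
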