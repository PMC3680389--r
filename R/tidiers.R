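#' Tidy a simulation result into block summaries
#'
#' One row per treatment and round block, with the block mean contribution,
#' punishment frequency and intensity over the block's rounds, and mean net
#' earnings per member per round — the standard summary panel of this
#' experimental design.
#'
#' @param x A `norm_sim` object.
#' @param blocks Character vector of `"first-last"` block labels.
#' @param ... Unused.
#' @return A tibble with columns `treatment`, `block`, `mean_contribution`,
#'   `punishment_frequency`, `punishment_intensity`, `mean_earnings`.
#' @examples
#' sim <- run_experiment(simulation_config(n_groups = 2, replications = 2, seed = 5))
#' tidy(sim)
#' @method tidy norm_sim
#' @export
tidy.norm_sim <- function(x, blocks = default_blocks, ...) {
  bm <- block_means(x, blocks)
  earn <- earnings_summary(x, blocks)
  pf <- purrr::map_dfr(blocks, function(b) {
    r <- parse_block(b)
    dplyr::mutate(
      dplyr::left_join(
        dplyr::select(punishment_frequency(x, r), "treatment", frequency_b = "frequency"),
        dplyr::select(punishment_intensity(x, r), "treatment", intensity_b = "intensity"),
        by = "treatment"
      ),
      block = b
    )
  })
  bm |>
    dplyr::left_join(earn, by = c("treatment", "block")) |>
    dplyr::left_join(pf, by = c("treatment", "block")) |>
    dplyr::rename(punishment_frequency = "frequency_b",
                  punishment_intensity = "intensity_b")
}

#' One-row summary of a simulation result
#'
#' @param x A `norm_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: design dimensions, master seed, overall mean
#'   contribution and total punishing acts.
#' @method glance norm_sim
#' @export
glance.norm_sim <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    n_treatments = length(cfg$treatments),
    replications = cfg$replications,
    n_groups = cfg$n_groups,
    rounds = cfg$game$rounds,
    agent_rounds = nrow(x$rounds),
    seed = cfg$seed,
    mean_contribution = mean(x$rounds$contribution),
    punishing_acts = nrow(x$acts)
  )
}
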