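sim_keys <- c("n_groups", "replications", "seed", "cooperate_contribution",
              "treatments", "instrument_rounds")

config_to_list <- function(cfg) {
  agents <- unclass(cfg$agents)
  agents$weights <- unclass(agents$weights)
  list(
    game = unclass(cfg$game),
    agents = agents,
    sim = list(
      n_groups = cfg$n_groups, replications = cfg$replications, seed = cfg$seed,
      cooperate_contribution = cfg$cooperate_contribution,
      treatments = cfg$treatments, instrument_rounds = cfg$instrument_rounds
    )
  )
}

check_keys <- function(given, allowed, where) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown %s key(s): %s", where, paste(unknown, collapse = ", ")))
  }
}

build_config <- function(lst) {
  lst <- lst %||% list()
  check_keys(lst, c("game", "agents", "sim"), "top-level")
  game_args <- lst$game %||% list()
  check_keys(game_args, names(formals(game_config)), "game")
  game <- do.call(game_config, game_args)

  agent_args <- lst$agents %||% list()
  check_keys(agent_args, names(formals(agent_params)), "agents")
  if (!is.null(agent_args$weights)) {
    check_keys(agent_args$weights, names(formals(salience_weights)), "agents$weights")
    agent_args$weights <- do.call(salience_weights, agent_args$weights)
  }
  agents <- do.call(agent_params, agent_args)

  sim_args <- lst$sim %||% list()
  check_keys(sim_args, sim_keys, "sim")
  if (!is.null(sim_args$instrument_rounds)) {
    ir <- sim_args$instrument_rounds
    if (is.character(ir) && length(ir) == 1) ir <- parse_block(ir)
    sim_args$instrument_rounds <- as.integer(unlist(ir))
  }
  if (!is.null(sim_args$treatments)) sim_args$treatments <- unlist(sim_args$treatments)
  do.call(simulation_config, c(list(game = game, agents = agents), sim_args))
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file may hold up to three sections — `game`, `agents` (with an
#' optional `weights` subsection) and `sim` — whose keys mirror the
#' arguments of [game_config()], [agent_params()], [salience_weights()] and
#' [simulation_config()]. Missing keys take the documented defaults; an
#' empty file yields the full default configuration; unknown keys are
#' rejected by name. `sim$instrument_rounds` may be given as a vector or as
#' a `"first-last"` string.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build_config(lst)
}

#' Write a configuration snapshot beside a run
#'
#' Serializes a [simulation_config()] (including the full salience weight
#' table and the master seed) to JSON in the same schema that
#' [load_config()] reads, so the snapshot alone suffices to reproduce the
#' run exactly.
#'
#' @param cfg A [simulation_config()].
#' @param path Output path for the JSON snapshot.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  if (!inherits(cfg, "simulation_config")) abort("`cfg` must be a simulation_config()")
  jsonlite::write_json(config_to_list(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Long-format round records
#'
#' `export_rounds()` shapes a simulation result into the canonical
#' long-format agent-round table (one row per treatment, replication,
#' group, round, agent) with the message rendered as the demanded amount
#' and reason; `write_rounds_csv()` writes it to CSV and
#' `read_rounds_csv()` reads and validates such a file. Write then read is
#' lossless, including the salience and individual-drive traces.
#'
#' @param x A `norm_sim` object (or, for `write_rounds_csv`, a data frame
#'   already in export shape).
#' @param path CSV path.
#' @param include_traces Include the per-agent `salience` and
#'   `individual_drive` columns (default `TRUE`).
#' @param cfg A [game_config()] used to validate ranges on read.
#' @return `export_rounds()` and `read_rounds_csv()` return the agent-round
#'   tibble; `write_rounds_csv()` returns `path` invisibly.
#' @examples
#' sim <- run_experiment(simulation_config(n_groups = 1, replications = 1, seed = 3))
#' head(export_rounds(sim))
#' @export
export_rounds <- function(x, include_traces = TRUE) {
  if (!inherits(x, "norm_sim")) abort("`x` must be a norm_sim object")
  amount <- x$config$cooperate_contribution
  out <- x$rounds |>
    dplyr::mutate(
      treatment = as.character(.data$treatment),
      msg_amount = ifelse(.data$msg_sent, amount, NA_real_),
      msg_reason = ifelse(.data$msg_sent, "JOINT_BENEFIT", NA_character_)
    ) |>
    dplyr::select("treatment", "replication", "group", "round", "agent",
                  "contribution", "points_sent", "points_received",
                  "msg_amount", "msg_reason", "stage1_payoff", "final_payoff",
                  "salience", "individual_drive")
  if (!include_traces) out <- dplyr::select(out, -"salience", -"individual_drive")
  out
}

#' @rdname export_rounds
#' @export
write_rounds_csv <- function(x, path, include_traces = TRUE) {
  tbl <- if (is.data.frame(x)) x else export_rounds(x, include_traces)
  readr::write_csv(tbl, path, na = "")
  invisible(path)
}

#' @rdname export_rounds
#' @export
read_rounds_csv <- function(path, cfg = game_config()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, na = "",
                         col_types = readr::cols(
                           treatment = readr::col_character(),
                           replication = readr::col_integer(),
                           group = readr::col_integer(),
                           round = readr::col_integer(),
                           agent = readr::col_integer(),
                           msg_reason = readr::col_character(),
                           msg_amount = readr::col_double()
                         ))
  required <- c("treatment", "replication", "group", "round", "agent",
                "contribution", "points_sent", "points_received",
                "stage1_payoff", "final_payoff")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("round records are missing column(s): %s", paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(tbl$contribution) | tbl$contribution < 0 |
                 tbl$contribution > cfg$endowment |
                 tbl$contribution != round(tbl$contribution))
  if (length(bad) > 0) {
    abort(sprintf("invalid contribution at data row %d: must be an integer in [0, %d]",
                  bad[1], cfg$endowment))
  }
  bad_pts <- which(tbl$points_sent < 0 | tbl$points_received < 0)
  if (length(bad_pts) > 0) {
    abort(sprintf("negative punishment totals at data row %d", bad_pts[1]))
  }
  tbl
}
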