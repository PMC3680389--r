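#' Initialize the state of one group of agents
#'
#' Agents start from uninformative priors: individual drive and norm
#' salience both at their configured initial values (0.5 by default), no
#' payoff history, and no defection history.
#'
#' @param cfg A [simulation_config()].
#' @return A group-state list consumed and returned by [play_round()].
#' @export
init_group_state <- function(cfg) {
  n <- cfg$game$group_size
  list(
    round = 1L,
    salience = rep(cfg$agents$init_salience, n),
    drive = rep(cfg$agents$init_drive, n),
    last_payoff = rep(NA_real_, n),
    prev_defect = rep(FALSE, n)
  )
}

# One round of one group, lean representation (used directly by the runner).
# Event order: (1) cooperation draws; (2) contributions revealed and stage-1
# payoffs computed; (3) punishment draws per sender per defecting target and
# message draws, where the phase permits; (4) payoff accounting; (5) each
# agent builds its cue vector from what it observed and updates salience and
# individual drive.
step_round <- function(state, phase, cfg) {
  game <- cfg$game
  par <- cfg$agents
  w <- par$weights
  n <- game$group_size
  norm_started <- length(cfg$instrument_rounds) > 0 &&
    state$round >= min(cfg$instrument_rounds)

  # (1)-(2) cooperate or defect, reveal contributions
  pcoop <- par$individual_weight * state$drive + par$normative_weight * state$salience
  coop <- runif(n) < pcoop
  contrib <- ifelse(coop, cfg$cooperate_contribution, 0)
  stage1 <- game$endowment - contrib + game$mpcr * sum(contrib)

  # (3) punishment: each agent draws one punish decision per defecting other
  points <- matrix(0, n, n)
  defect <- !coop
  if (phase$punish_on && any(defect)) {
    for (s in seq_len(n)) {
      def_others <- defect
      def_others[s] <- FALSE
      d <- sum(def_others)
      if (d == 0) next
      p <- par$initial_punishment_prob * (1 - (d - 1) / (n - 1))
      targets <- which(def_others)
      hit <- runif(d) < p
      if (any(hit)) {
        pts <- ifelse(state$prev_defect[targets], par$high_points, par$low_points)
        points[s, targets[hit]] <- pts[hit]
      }
    }
  }
  msg <- if (phase$msg_on) runif(n) < state$salience else rep(FALSE, n)

  # (4) payoff accounting
  p_sent <- rowSums(points)
  p_recv <- colSums(points)
  final <- stage1 - game$sender_cost * p_sent - game$target_cost * p_recv

  # (5a) cue vectors, vectorized over observers (own acts are excluded from
  # the observed counts; acts on oneself are observed like any other)
  acts_by <- rowSums(points > 0)
  bare_total <- sum(acts_by[!msg])
  sanct_total <- sum(acts_by[msg])
  bare <- bare_total - acts_by * (!msg)
  sanct <- sanct_total - acts_by * msg
  pure_msg <- msg & acts_by == 0
  msgs <- sum(pure_msg) - pure_msg
  obs_comp <- sum(coop) - coop
  obs_viol <- sum(defect) - defect
  if (norm_started) {
    viol_unp <- defect & p_recv == 0
    unp <- sum(viol_unp) - viol_unp
  } else {
    unp <- 0
  }
  delta <- (w$own_compliance * coop + w$own_violation * defect +
              w$observed_compliance * obs_comp + w$observed_violation * obs_viol +
              w$punishments_observed * bare + w$sanctions_observed * sanct +
              w$messages_received * msgs + w$unpunished_violations * unp) / w$lambda
  no_signal <- (bare + sanct + msgs) == 0
  if (any(no_signal)) {
    fade <- if (par$forgetting_model == "decay") {
      par$forgetting_prob * par$decay_step
    } else {
      (runif(n) < par$forgetting_prob) * par$decay_step
    }
    delta[no_signal] <- delta[no_signal] - (fade * no_signal)[no_signal]
  }
  salience <- clamp01(state$salience + delta)

  # (5b) winner-stay losers-change on the individual drive (needs two payoffs)
  drive <- state$drive
  if (!anyNA(state$last_payoff)) {
    scale <- game$endowment * game$group_size * game$mpcr
    step <- par$learning_rate * abs(final - state$last_payoff) / scale
    winner <- final >= state$last_payoff
    dir <- ifelse(winner == coop, 1, -1)
    drive <- clamp01(drive + dir * step)
  }

  list(
    ledger = list(round = state$round, coop = coop, contributions = contrib,
                  points = points, msg = msg, stage1 = stage1,
                  points_sent = p_sent, points_received = p_recv, final = final),
    state = list(round = state$round + 1L, salience = salience, drive = drive,
                 last_payoff = final, prev_defect = defect)
  )
}

#' Play one round of one group
#'
#' Runs one full round for a single group under the given phase: cooperation
#' draws from the two-drive policy, contribution revelation, punishment and
#' message draws where the phase permits, payoff accounting, and the
#' end-of-round salience and individual-drive updates. Randomness comes from
#' the current R RNG state, so a fixed `set.seed()` gives identical rounds.
#'
#' @param state A group state from [init_group_state()] (or a previous call).
#' @param phase A phase from [treatment_phase()].
#' @param cfg A [simulation_config()].
#' @return A list with elements `ledger` (a [round_ledger()] with punishment
#'   applied, plus a `msg_sent` logical attribute) and `state` (the updated
#'   group state, including post-round `salience` and `drive`).
#' @examples
#' cfg <- simulation_config(replications = 1, n_groups = 1)
#' set.seed(1)
#' out <- play_round(init_group_state(cfg), treatment_phase("sanction", 1, cfg), cfg)
#' out$ledger
#' @export
play_round <- function(state, phase, cfg) {
  out <- step_round(state, phase, cfg)
  led <- out$ledger
  messages <- lapply(which(led$msg), function(s) {
    norm_message(s, cfg$cooperate_contribution, "JOINT_BENEFIT")
  })
  ledger <- round_ledger(led$round, led$contributions,
                         points = led$points, messages = messages,
                         cfg = cfg$game)
  ledger <- apply_punishment(ledger)
  ledger$msg_sent <- led$msg
  list(ledger = ledger, state = out$state)
}

child_seed <- function(master, index) {
  m <- 2147483563
  h <- master %% m
  h <- (h * 69621) %% m
  h <- (h + index) %% m
  h <- (h * 69621) %% m
  as.integer(h)
}

#' Run a replicated simulation experiment
#'
#' Runs every configured treatment for `replications` independent
#' replications of `n_groups` fixed groups over the full round schedule.
#' Each (treatment, replication, group) triple plays on its own RNG
#' substream derived deterministically from the master seed, so an
#' identical master seed yields a bit-identical result regardless of how
#' runs might be split up.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `norm_sim`: a list with
#'   \describe{
#'     \item{`rounds`}{agent-round panel (tibble): `treatment`,
#'       `replication`, `group`, `round`, `agent`, `contribution`,
#'       `points_sent`, `points_received`, `msg_sent`, `stage1_payoff`,
#'       `final_payoff`, `salience`, `individual_drive`.}
#'     \item{`acts`}{nonzero punishing acts (tibble): `treatment`,
#'       `replication`, `group`, `round`, `sender`, `target`, `points`.}
#'     \item{`config`}{the configuration used.}
#'   }
#' @examples
#' sim <- run_experiment(simulation_config(n_groups = 1, replications = 1, seed = 7))
#' dplyr::count(sim$rounds, treatment)
#' @export
run_experiment <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config")) abort("`cfg` must be a simulation_config()")
  game <- cfg$game
  n <- game$group_size
  rounds <- game$rounds
  treatments <- cfg$treatments
  n_runs <- length(treatments) * cfg$replications * cfg$n_groups
  n_rows <- n_runs * rounds * n

  col_t <- integer(n_rows); col_rep <- integer(n_rows); col_g <- integer(n_rows)
  col_round <- integer(n_rows); col_agent <- integer(n_rows)
  col_contrib <- numeric(n_rows); col_sent <- numeric(n_rows)
  col_recv <- numeric(n_rows); col_msg <- logical(n_rows)
  col_stage1 <- numeric(n_rows); col_final <- numeric(n_rows)
  col_sal <- numeric(n_rows); col_drv <- numeric(n_rows)

  acts_list <- vector("list", n_runs)
  agent_idx <- seq_len(n)
  run_index <- 0L
  pos <- 0L
  for (ti in seq_along(treatments)) {
    treatment <- treatments[ti]
    phases <- lapply(seq_len(rounds), function(r) treatment_phase(treatment, r, cfg))
    for (rep_i in seq_len(cfg$replications)) {
      for (g in seq_len(cfg$n_groups)) {
        run_index <- run_index + 1L
        set.seed(child_seed(cfg$seed, run_index))
        state <- init_group_state(cfg)
        run_acts <- NULL
        for (r in seq_len(rounds)) {
          out <- step_round(state, phases[[r]], cfg)
          led <- out$ledger
          state <- out$state
          idx <- pos + agent_idx
          col_t[idx] <- ti; col_rep[idx] <- rep_i; col_g[idx] <- g
          col_round[idx] <- r; col_agent[idx] <- agent_idx
          col_contrib[idx] <- led$contributions
          col_sent[idx] <- led$points_sent; col_recv[idx] <- led$points_received
          col_msg[idx] <- led$msg
          col_stage1[idx] <- led$stage1; col_final[idx] <- led$final
          col_sal[idx] <- state$salience; col_drv[idx] <- state$drive
          pos <- pos + n
          if (any(led$points > 0)) {
            nz <- which(led$points > 0, arr.ind = TRUE)
            run_acts <- rbind(run_acts, cbind(ti, rep_i, g, r, nz[, 1], nz[, 2],
                                              led$points[nz]))
          }
        }
        acts_list[[run_index]] <- run_acts
      }
    }
  }
  acts_mat <- do.call(rbind, acts_list)
  if (is.null(acts_mat)) acts_mat <- matrix(numeric(0), ncol = 7)
  acts <- tibble::tibble(
    treatment = factor(treatments[acts_mat[, 1]], levels = treatments),
    replication = as.integer(acts_mat[, 2]), group = as.integer(acts_mat[, 3]),
    round = as.integer(acts_mat[, 4]), sender = as.integer(acts_mat[, 5]),
    target = as.integer(acts_mat[, 6]), points = as.integer(acts_mat[, 7])
  )
  rounds_tbl <- tibble::tibble(
    treatment = factor(treatments[col_t], levels = treatments),
    replication = col_rep, group = col_g, round = col_round, agent = col_agent,
    contribution = col_contrib, points_sent = col_sent,
    points_received = col_recv, msg_sent = col_msg,
    stage1_payoff = col_stage1, final_payoff = col_final,
    salience = col_sal, individual_drive = col_drv
  )
  structure(list(rounds = rounds_tbl, acts = acts, config = cfg),
            class = "norm_sim")
}

#' @export
print.norm_sim <- function(x, ...) {
  cfg <- x$config
  cat("<norm_sim>\n")
  cat(sprintf("  treatments: %s\n", paste(cfg$treatments, collapse = ", ")))
  cat(sprintf("  %d groups x %d replications x %d rounds (%d agent-rounds), seed %d\n",
              cfg$n_groups, cfg$replications, cfg$game$rounds,
              nrow(x$rounds), cfg$seed))
  cat(sprintf("  %d punishing acts recorded\n", nrow(x$acts)))
  invisible(x)
}
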