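#' Economic constants of the public-goods game
#'
#' Bundles every monetary constant of the repeated public-goods game with
#' costly punishment: each of `group_size` members privately splits an
#' `endowment` (in ECU, experimental currency units) between a private
#' account and a group account that pays `mpcr` ECU back to every member per
#' ECU contributed. In instrumented rounds a member may assign up to
#' `max_points` punishment points to each other member; each point costs the
#' sender `sender_cost` ECU and the target `target_cost` ECU. Accumulated
#' ECU (plus the `show_up` payment) convert to currency at `exchange_rate`
#' ECU per unit.
#'
#' The social-dilemma condition `mpcr < 1 < mpcr * group_size` is enforced:
#' contributing is individually dominated but collectively optimal.
#'
#' @param endowment Integer ECU endowment per member per round.
#' @param mpcr Marginal per-capita return: ECU returned to each member per
#'   ECU contributed to the group account.
#' @param group_size Number of members per group.
#' @param max_points Maximum punishment points one sender may assign to one
#'   target in one round.
#' @param sender_cost ECU cost per point borne by the punisher.
#' @param target_cost ECU cost per point borne by the punished member.
#' @param exchange_rate ECU per currency unit at settlement.
#' @param show_up Initial ECU payment.
#' @param rounds Total number of rounds.
#' @return An object of class `game_config` (a validated named list).
#' @examples
#' cfg <- game_config()
#' stage1_payoffs(c(0, 20, 20, 20), cfg)
#' @export
game_config <- function(endowment = 20L, mpcr = 0.4, group_size = 4L,
                        max_points = 10L, sender_cost = 1, target_cost = 3,
                        exchange_rate = 40, show_up = 200, rounds = 30L) {
  cfg <- list(
    endowment = as.integer(endowment), mpcr = as.numeric(mpcr),
    group_size = as.integer(group_size), max_points = as.integer(max_points),
    sender_cost = as.numeric(sender_cost), target_cost = as.numeric(target_cost),
    exchange_rate = as.numeric(exchange_rate), show_up = as.numeric(show_up),
    rounds = as.integer(rounds)
  )
  if (anyNA(unlist(cfg))) abort("game_config: all fields must be non-missing numbers")
  if (!(cfg$mpcr < 1 && cfg$mpcr * cfg$group_size > 1)) {
    abort(sprintf(
      "game_config: social-dilemma condition violated, need mpcr < 1 < mpcr * group_size (mpcr = %g, group_size = %d)",
      cfg$mpcr, cfg$group_size
    ))
  }
  positive <- c("endowment", "group_size", "max_points", "sender_cost",
                "target_cost", "exchange_rate", "rounds")
  for (f in positive) {
    if (cfg[[f]] <= 0) abort(sprintf("game_config: `%s` must be strictly positive", f))
  }
  if (cfg$show_up < 0) abort("game_config: `show_up` must be non-negative")
  structure(cfg, class = "game_config")
}

#' Signed cue weights of the norm-salience mechanism
#'
#' Norm salience is updated each round from a weighted sum of behavioural
#' and communicative cues, divided by the normalizer `lambda`.
#' Compliance-type cues (own compliance, observed compliance, punishments,
#' sanctions, messages) must carry non-negative weights; violation-type cues
#' (own violation, observed violation, unpunished violations) non-positive
#' ones. A sanction (punishment accompanied by a normative message) is a
#' stronger norm signal than bare punishment, so its default weight is
#' larger.
#'
#' @param own_compliance,observed_compliance,punishments_observed,sanctions_observed,messages_received
#'   Non-negative weights of the compliance-type cues.
#' @param own_violation,observed_violation,unpunished_violations Non-positive
#'   weights of the violation-type cues.
#' @param lambda Positive normalizer dividing the weighted cue sum; the
#'   default, 12, is three times the default group size.
#' @return An object of class `salience_weights`.
#' @export
salience_weights <- function(own_compliance = 0.99, own_violation = -0.99,
                             observed_compliance = 0.33, observed_violation = -0.33,
                             punishments_observed = 0.33, sanctions_observed = 0.99,
                             messages_received = 0.99, unpunished_violations = -0.66,
                             lambda = 12) {
  w <- list(
    own_compliance = own_compliance, own_violation = own_violation,
    observed_compliance = observed_compliance, observed_violation = observed_violation,
    punishments_observed = punishments_observed, sanctions_observed = sanctions_observed,
    messages_received = messages_received, unpunished_violations = unpunished_violations,
    lambda = lambda
  )
  w <- lapply(w, as.numeric)
  if (anyNA(unlist(w))) abort("salience_weights: all weights must be numbers")
  pos <- c("own_compliance", "observed_compliance", "punishments_observed",
           "sanctions_observed", "messages_received")
  neg <- c("own_violation", "observed_violation", "unpunished_violations")
  for (f in pos) if (w[[f]] < 0) {
    abort(sprintf("salience_weights: compliance-type cue `%s` must have a non-negative weight", f))
  }
  for (f in neg) if (w[[f]] > 0) {
    abort(sprintf("salience_weights: violation-type cue `%s` must have a non-positive weight", f))
  }
  if (w$lambda <= 0) abort("salience_weights: `lambda` must be positive")
  structure(w, class = "salience_weights")
}

#' Agent parameters of the norm-psychology model
#'
#' The cooperation probability of an agent is the convex combination
#' `individual_weight * ID + normative_weight * ND` of its individual drive
#' (payoff learning) and normative drive (norm salience). The headline
#' defaults — individual weight 0.5, normative weight 0.5, initial
#' punishment probability 0.5, forgetting probability 0.3 — are the
#' reference parameterization of the simulation experiment.
#'
#' Punishment intensity is binary: `low_points` for a first-time defector,
#' `high_points` for a repeat offender. The cost of being punished must
#' exceed the net cost of cooperating, i.e.
#' `target_cost * low_points > endowment * (1 - mpcr)`; this cross-check
#' against the game constants is enforced by [simulation_config()].
#'
#' @param individual_weight,normative_weight Weights of the two drives;
#'   must sum to 1.
#' @param initial_punishment_prob Probability of punishing a lone defector.
#' @param forgetting_prob Forgetting probability: scales the salience decay
#'   applied in rounds carrying no norm-signalling cues.
#' @param learning_rate Step-size of the winner-stay losers-change update of
#'   the individual drive, in (0, 1].
#' @param low_points,high_points Binary punishment intensities, in points.
#' @param init_drive,init_salience Initial individual drive and salience
#'   (uninformative priors, 0.5).
#' @param decay_step Base salience decay per no-signal round, multiplied by
#'   `forgetting_prob`.
#' @param forgetting_model `"decay"` (deterministic step, default) or
#'   `"bernoulli"` (full `decay_step` applied with probability
#'   `forgetting_prob`).
#' @param weights A [salience_weights()] object.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(individual_weight = 0.5, normative_weight = 0.5,
                         initial_punishment_prob = 0.5, forgetting_prob = 0.3,
                         learning_rate = 0.1, low_points = 5L, high_points = 10L,
                         init_drive = 0.5, init_salience = 0.5,
                         decay_step = 0.05,
                         forgetting_model = c("decay", "bernoulli"),
                         weights = salience_weights()) {
  p <- list(
    individual_weight = as.numeric(individual_weight),
    normative_weight = as.numeric(normative_weight),
    initial_punishment_prob = as.numeric(initial_punishment_prob),
    forgetting_prob = as.numeric(forgetting_prob),
    learning_rate = as.numeric(learning_rate),
    low_points = as.integer(low_points), high_points = as.integer(high_points),
    init_drive = as.numeric(init_drive), init_salience = as.numeric(init_salience),
    decay_step = as.numeric(decay_step),
    forgetting_model = match.arg(forgetting_model),
    weights = weights
  )
  unit <- c("individual_weight", "normative_weight", "initial_punishment_prob",
            "forgetting_prob", "init_drive", "init_salience")
  for (f in unit) {
    if (is.na(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      abort(sprintf("agent_params: `%s` must lie in [0, 1]", f))
    }
  }
  if (abs(p$individual_weight + p$normative_weight - 1) > 1e-8) {
    abort("agent_params: `individual_weight` and `normative_weight` must sum to 1")
  }
  if (p$learning_rate <= 0 || p$learning_rate > 1) {
    abort("agent_params: `learning_rate` must lie in (0, 1]")
  }
  if (!(p$low_points > 0 && p$low_points < p$high_points)) {
    abort("agent_params: need 0 < low_points < high_points")
  }
  if (!inherits(p$weights, "salience_weights")) {
    abort("agent_params: `weights` must be a salience_weights() object")
  }
  structure(p, class = "agent_params")
}

#' Full configuration of a replicated simulation experiment
#'
#' Combines the game constants, the agent parameters and the experiment
#' design: how many fixed groups play each treatment, how many independent
#' replications of the whole session are run, and the three-block schedule
#' (baseline rounds, instrumented rounds, baseline again). Cooperating
#' agents contribute `cooperate_contribution` ECU (the full endowment by
#' default); defectors contribute nothing.
#'
#' Validation cross-checks the agent and game parameters: punishment
#' intensities must respect the per-target cap, and the cost of being
#' punished at the low intensity must exceed the net cost of cooperating,
#' `target_cost * low_points > endowment * (1 - mpcr)`, so that punishment
#' can make defection instrumentally unattractive.
#'
#' @param game A [game_config()].
#' @param agents An [agent_params()].
#' @param n_groups Groups per treatment per replication.
#' @param replications Independent replications of the whole experiment.
#' @param seed Master seed; every replication/group derives its own
#'   substream from it.
#' @param cooperate_contribution ECU contributed when an agent cooperates.
#' @param treatments Character vector drawn from `"punishment"`,
#'   `"message"`, `"sanction"`, `"none"` (a no-instrument control arm).
#' @param instrument_rounds Integer vector of rounds in which treatment
#'   instruments are available (default 11:20).
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_groups = 2, replications = 2)
#' @export
simulation_config <- function(game = game_config(), agents = agent_params(),
                              n_groups = 12L, replications = 100L, seed = 1L,
                              cooperate_contribution = NULL,
                              treatments = c("punishment", "message", "sanction"),
                              instrument_rounds = 11:20) {
  if (!inherits(game, "game_config")) abort("simulation_config: `game` must be a game_config()")
  if (!inherits(agents, "agent_params")) abort("simulation_config: `agents` must be an agent_params()")
  cooperate_contribution <- cooperate_contribution %||% game$endowment
  cfg <- list(
    game = game, agents = agents,
    n_groups = as.integer(n_groups), replications = as.integer(replications),
    seed = as.integer(seed),
    cooperate_contribution = as.numeric(cooperate_contribution),
    treatments = as.character(treatments),
    instrument_rounds = as.integer(instrument_rounds)
  )
  if (cfg$n_groups < 1 || cfg$replications < 1) {
    abort("simulation_config: `n_groups` and `replications` must be >= 1")
  }
  if (!(cfg$cooperate_contribution > 0 && cfg$cooperate_contribution <= game$endowment)) {
    abort("simulation_config: `cooperate_contribution` must lie in (0, endowment]")
  }
  bad <- setdiff(cfg$treatments, c("punishment", "message", "sanction", "none"))
  if (length(bad) > 0 || length(cfg$treatments) == 0 || anyDuplicated(cfg$treatments)) {
    abort("simulation_config: `treatments` must be distinct values among punishment, message, sanction, none")
  }
  if (length(cfg$instrument_rounds) > 0 &&
      (min(cfg$instrument_rounds) < 1 || max(cfg$instrument_rounds) > game$rounds)) {
    abort("simulation_config: `instrument_rounds` must lie within 1..rounds")
  }
  if (agents$high_points > game$max_points) {
    abort("simulation_config: `high_points` exceeds the per-target cap `max_points`")
  }
  if (!(game$target_cost * agents$low_points > game$endowment * (1 - game$mpcr))) {
    abort(paste0(
      "simulation_config: cost of being punished must exceed the net cost of cooperating ",
      "(need target_cost * low_points > endowment * (1 - mpcr))"
    ))
  }
  structure(cfg, class = "simulation_config")
}

#' Which instruments are live for a treatment in a given round?
#'
#' Rounds outside `instrument_rounds` are baseline for every treatment.
#' Inside them, the punishment treatment enables material punishment only,
#' the message treatment enables normative messages only, the sanction
#' treatment enables both, and the `"none"` control arm enables neither.
#'
#' @param treatment One of `"punishment"`, `"message"`, `"sanction"`, `"none"`.
#' @param round Round index.
#' @param cfg A [simulation_config()].
#' @return A list with logical elements `punish_on` and `msg_on`.
#' @export
treatment_phase <- function(treatment, round, cfg) {
  treatment <- match.arg(treatment, c("punishment", "message", "sanction", "none"))
  on <- round %in% cfg$instrument_rounds
  list(
    punish_on = on && treatment %in% c("punishment", "sanction"),
    msg_on = on && treatment %in% c("message", "sanction")
  )
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  cat(sprintf("  endowment %d ECU, MPCR %g, groups of %d, %d rounds\n",
              x$endowment, x$mpcr, x$group_size, x$rounds))
  cat(sprintf("  punishment: up to %d points/target, %g:%g sender:target cost\n",
              x$max_points, x$sender_cost, x$target_cost))
  cat(sprintf("  settlement: %g ECU show-up, %g ECU per currency unit\n",
              x$show_up, x$exchange_rate))
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  treatments: %s\n", paste(x$treatments, collapse = ", ")))
  cat(sprintf("  %d groups x %d replications, master seed %d\n",
              x$n_groups, x$replications, x$seed))
  cat(sprintf("  instrument rounds %d-%d of %d; cooperators contribute %g ECU\n",
              min(x$instrument_rounds), max(x$instrument_rounds),
              x$game$rounds, x$cooperate_contribution))
  invisible(x)
}
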