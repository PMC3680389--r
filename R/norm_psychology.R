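#' Per-round cue counts observed by one agent
#'
#' Everything one agent learns in one round that bears on the cooperation
#' norm: its own compliance or violation (exactly one of the two in any
#' played round), the compliance and violations it observed among the other
#' members, punishing acts it observed (split into bare punishments and
#' sanctions, i.e. punishments whose sender also sent a normative message),
#' pure messages received, and violations that went entirely unpunished.
#'
#' @param own_compliance,own_violation 0/1 indicators; must sum to 1 for a
#'   played round.
#' @param observed_compliance,observed_violation Counts among the other
#'   members.
#' @param punishments_observed Bare punishing acts (sender sent no message).
#' @param sanctions_observed Punishing acts whose sender also messaged.
#' @param messages_received Messages from senders who did not punish.
#' @param unpunished_violations Defecting members who received no points.
#' @return An object of class `cue_vector` (a named integer vector).
#' @export
cue_vector <- function(own_compliance = 0L, own_violation = 0L,
                       observed_compliance = 0L, observed_violation = 0L,
                       punishments_observed = 0L, sanctions_observed = 0L,
                       messages_received = 0L, unpunished_violations = 0L) {
  x <- c(own_compliance = own_compliance, own_violation = own_violation,
         observed_compliance = observed_compliance,
         observed_violation = observed_violation,
         punishments_observed = punishments_observed,
         sanctions_observed = sanctions_observed,
         messages_received = messages_received,
         unpunished_violations = unpunished_violations)
  if (anyNA(x) || any(x < 0)) abort("cue_vector: counts must be non-negative")
  if (any(x != round(x))) abort("cue_vector: counts must be integers")
  if (any(c(own_compliance, own_violation) > 1)) {
    abort("cue_vector: own_compliance and own_violation are 0/1 indicators")
  }
  structure(as.integer(x), names = names(x), class = "cue_vector")
}

cue_names <- c("own_compliance", "own_violation", "observed_compliance",
               "observed_violation", "punishments_observed", "sanctions_observed",
               "messages_received", "unpunished_violations")

# cues that signal the norm itself (their absence triggers forgetting)
signal_cues <- c("punishments_observed", "sanctions_observed", "messages_received")

#' Update norm salience from one round of cues
#'
#' The salience value moves by the weighted cue sum divided by the
#' normalizer: `value' = clamp01(value + sum(w_c * x_c) / lambda)`. In a
#' round carrying no norm-signalling cues (no punishments, sanctions or
#' messages observed), salience additionally fades: under the default
#' deterministic model by `forgetting_prob * decay_step`, under the
#' Bernoulli model by the full `decay_step` with probability
#' `forgetting_prob`. The result is always clamped to `[0, 1]`.
#'
#' @param value Current salience in `[0, 1]`.
#' @param cues A [cue_vector()] (or named numeric vector of cue counts).
#' @param weights A [salience_weights()].
#' @param forgetting_prob Forgetting probability in `[0, 1]`.
#' @param decay_step Base decay per no-signal round.
#' @param forgetting_model `"decay"` or `"bernoulli"`.
#' @return The updated salience value in `[0, 1]`.
#' @examples
#' w <- salience_weights()
#' update_salience(0.5, cue_vector(observed_compliance = 3, messages_received = 2), w, 0.3)
#' @export
update_salience <- function(value, cues, weights = salience_weights(),
                            forgetting_prob = 0.3, decay_step = 0.05,
                            forgetting_model = c("decay", "bernoulli")) {
  forgetting_model <- match.arg(forgetting_model)
  if (is.na(value) || value < 0 || value > 1) abort("`value` must lie in [0, 1]")
  x <- cues[cue_names]
  if (anyNA(x)) abort(sprintf("`cues` must provide counts named %s", paste(cue_names, collapse = ", ")))
  if (any(x < 0)) abort("cue counts must be non-negative")
  w <- unlist(weights[cue_names])
  delta <- sum(w * as.numeric(x)) / weights$lambda
  if (sum(x[signal_cues]) == 0) {
    delta <- delta - switch(forgetting_model,
      decay = forgetting_prob * decay_step,
      bernoulli = if (runif(1) < forgetting_prob) decay_step else 0
    )
  }
  clamp01(value + delta)
}

#' Winner-stay losers-change update of the individual drive
#'
#' The individual drive is the payoff-learned propensity to cooperate. If
#' the last payoff was at least as high as the one before (a "winner"), the
#' drive moves toward the propensity of the last action — toward 1 after
#' cooperating, toward 0 after defecting — by
#' `learning_rate * |payoff change| / payoff_scale`; if the payoff dropped
#' (a "loser"), it moves away from that action by the same step. The result
#' is clamped to `[0, 1]`, and an unchanged payoff moves nothing.
#'
#' @param drive Current drive in `[0, 1]`.
#' @param last_action `"C"` or `"D"`, the action that produced `last_payoff`.
#' @param last_payoff,prev_payoff Final ECU payoffs of the last two rounds.
#' @param learning_rate Step-size in (0, 1].
#' @param payoff_scale Normalizes the payoff change; the default,
#'   `endowment * group_size * mpcr` of the standard game, keeps per-round
#'   movement well below 1.
#' @return The updated drive in `[0, 1]`.
#' @examples
#' update_individual_drive(0.5, "D", 32, 0, learning_rate = 0.2, payoff_scale = 32)
#' @export
update_individual_drive <- function(drive, last_action, last_payoff, prev_payoff,
                                    learning_rate = 0.1, payoff_scale = 32) {
  if (learning_rate <= 0 || learning_rate > 1) abort("`learning_rate` must lie in (0, 1]")
  if (is.na(drive) || drive < 0 || drive > 1) abort("`drive` must lie in [0, 1]")
  last_action <- match.arg(last_action, c("C", "D"))
  if (anyNA(c(last_payoff, prev_payoff))) abort("both payoffs must be set")
  step <- learning_rate * abs(last_payoff - prev_payoff) / payoff_scale
  toward_c <- last_action == "C"
  winner <- last_payoff >= prev_payoff
  # winner moves toward the last action's propensity, loser away from it
  dir <- if (winner == toward_c) 1 else -1
  clamp01(drive + dir * step)
}

#' Cooperation probability from the two drives
#'
#' `P(C) = individual_weight * ID + normative_weight * ND`, a convex
#' combination, so the result is guaranteed to lie in `[0, 1]` and is
#' monotone non-decreasing in each drive (strictly increasing in the
#' normative drive whenever its weight is positive).
#'
#' @param individual_drive,normative_drive Drives in `[0, 1]`.
#' @param params An [agent_params()].
#' @return The cooperation probability.
#' @export
cooperation_probability <- function(individual_drive, normative_drive,
                                    params = agent_params()) {
  if (any(is.na(c(individual_drive, normative_drive))) ||
      any(c(individual_drive, normative_drive) < 0) ||
      any(c(individual_drive, normative_drive) > 1)) {
    abort("drives must lie in [0, 1]")
  }
  params$individual_weight * individual_drive + params$normative_weight * normative_drive
}

#' Normative drive from norm salience
#'
#' The motivation to comply tracks how prominent the norm currently is; the
#' default reading is the identity map, `ND = salience`.
#'
#' @param salience Salience value in `[0, 1]`.
#' @return The normative drive.
#' @export
normative_drive <- function(salience) {
  if (any(is.na(salience) | salience < 0 | salience > 1)) abort("`salience` must lie in [0, 1]")
  salience
}

#' Probability of punishing, given the number of defectors
#'
#' Nobody punishes when there is nobody to punish; a lone defector is
#' punished with the anchor probability `initial_punishment_prob`; beyond
#' that the probability decreases linearly in the defector count:
#' `P0 * (1 - (d - 1) / (group_size - 1))`. When many defect, the norm
#' looks weak and each violator is less likely to be punished.
#'
#' @param n_defectors Number of defectors among the other members, in
#'   `0..(group_size - 1)`.
#' @param params An [agent_params()].
#' @param group_size Group size.
#' @return The per-defector punishing probability.
#' @examples
#' punishment_probability(3, agent_params(), 4)  # 0.5 * (1 - 2/3)
#' @export
punishment_probability <- function(n_defectors, params = agent_params(), group_size = 4L) {
  if (any(is.na(n_defectors) | n_defectors < 0 | n_defectors > group_size - 1)) {
    abort(sprintf("`n_defectors` must lie in 0..%d", group_size - 1))
  }
  p0 <- params$initial_punishment_prob
  ifelse(n_defectors == 0, 0, p0 * (1 - (n_defectors - 1) / (group_size - 1)))
}

#' Probability of sending a normative message
#'
#' A direct (monotone non-decreasing) function of the perceived salience of
#' the norm; the default reading is the identity map.
#'
#' @param salience Salience value in `[0, 1]`.
#' @return The message probability.
#' @export
message_probability <- function(salience) {
  if (any(is.na(salience) | salience < 0 | salience > 1)) abort("`salience` must lie in [0, 1]")
  salience
}

#' Binary punishment intensity for a defecting target
#'
#' Punishment intensity is binary: a repeat offender — a target that also
#' defected in the immediately preceding round — receives `high_points`, a
#' first-time defector `low_points`.
#'
#' @param target_defected_now Did the target defect this round? Must be
#'   `TRUE`; punishing a cooperator is an error.
#' @param target_defected_before Did the target also defect in the previous
#'   round?
#' @param params An [agent_params()].
#' @return `low_points` or `high_points`.
#' @export
choose_intensity <- function(target_defected_now, target_defected_before,
                             params = agent_params()) {
  if (!isTRUE(target_defected_now)) abort("intensity is only defined for a defecting target")
  if (isTRUE(target_defected_before)) params$high_points else params$low_points
}
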