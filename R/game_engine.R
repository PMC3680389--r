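#' Stage-1 public-good payoffs
#'
#' Each member keeps the uncontributed part of the endowment and receives
#' `mpcr` ECU for every ECU in the group account:
#' `E_i = endowment - c_i + mpcr * sum(c)`. The group total therefore
#' satisfies the conservation identity
#' `sum(E) = group_size * endowment + (group_size * mpcr - 1) * sum(c)`.
#'
#' @param contributions Integer vector of length `group_size`, each entry in
#'   `[0, endowment]`.
#' @param cfg A [game_config()].
#' @return Numeric vector of stage-1 payoffs in ECU.
#' @examples
#' stage1_payoffs(c(20, 20, 20, 20), game_config())
#' @export
stage1_payoffs <- function(contributions, cfg = game_config()) {
  check_contributions(contributions, cfg)
  cfg$endowment - contributions + cfg$mpcr * sum(contributions)
}

check_contributions <- function(contributions, cfg) {
  if (length(contributions) != cfg$group_size) {
    abort(sprintf("expected %d contributions, got %d", cfg$group_size, length(contributions)))
  }
  bad <- which(is.na(contributions) | contributions < 0 |
                 contributions > cfg$endowment | contributions != round(contributions))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid contribution for member %s: must be an integer in [0, %d]",
      paste(bad, collapse = ", "), cfg$endowment
    ))
  }
  invisible(TRUE)
}

check_points <- function(points, cfg) {
  n <- cfg$group_size
  if (!is.matrix(points) || any(dim(points) != c(n, n))) {
    abort(sprintf("`points` must be a %d x %d sender-by-target matrix", n, n))
  }
  if (anyNA(points) || any(points < 0) || any(points != round(points))) {
    abort("`points` must be non-negative integers")
  }
  if (any(points > cfg$max_points)) {
    abort(sprintf("punishment points exceed the per-target cap of %d", cfg$max_points))
  }
  if (any(diag(points) != 0)) abort("self-punishment is not allowed (diagonal must be zero)")
  invisible(TRUE)
}

#' One group-round of decisions and payoff accounting
#'
#' A `round_ledger` holds one round of one group: the contribution vector,
#' the sender-by-target punishment-point matrix, any normative messages, and
#' (after [apply_punishment()]) the complete payoff accounting.
#'
#' @param round Round index.
#' @param contributions Integer contribution vector.
#' @param points Square sender-by-target matrix of punishment points
#'   (zero diagonal); defaults to all zeros.
#' @param messages List of [norm_message()] objects.
#' @param cfg A [game_config()].
#' @return An object of class `round_ledger` with stage-1 payoffs filled in
#'   and punishment accounting (`points_sent`, `points_received`,
#'   `final_payoffs`) left `NA` until [apply_punishment()] is called.
#' @examples
#' led <- round_ledger(1, c(20, 20, 20, 20))
#' apply_punishment(led)$final_payoffs
#' @export
round_ledger <- function(round, contributions, points = NULL, messages = list(),
                         cfg = game_config()) {
  n <- cfg$group_size
  if (is.null(points)) points <- matrix(0L, n, n)
  check_contributions(contributions, cfg)
  check_points(points, cfg)
  if (!is.list(messages) || !all(vapply(messages, inherits, logical(1), "norm_message"))) {
    abort("`messages` must be a list of norm_message() objects")
  }
  structure(list(
    round = as.integer(round),
    contributions = as.integer(contributions),
    points = points,
    messages = messages,
    stage1_payoffs = stage1_payoffs(contributions, cfg),
    points_sent = rep(NA_real_, n),
    points_received = rep(NA_real_, n),
    final_payoffs = rep(NA_real_, n),
    cfg = cfg
  ), class = "round_ledger")
}

#' Apply stage-2 punishment accounting to a ledger
#'
#' Fills in total points sent per member (row sums), points received
#' (column sums) and final payoffs
#' `final_i = E_i - sender_cost * sent_i - target_cost * received_i`.
#' Final payoffs may be negative. Punishment only destroys ECU: the group
#' loses exactly `(sender_cost + target_cost) * sum(points)`.
#'
#' @param ledger A [round_ledger()].
#' @param cfg A [game_config()]; defaults to the one stored in the ledger.
#' @return The ledger with `points_sent`, `points_received` and
#'   `final_payoffs` filled in.
#' @export
apply_punishment <- function(ledger, cfg = NULL) {
  if (!inherits(ledger, "round_ledger")) abort("`ledger` must be a round_ledger()")
  cfg <- cfg %||% ledger$cfg
  check_points(ledger$points, cfg)
  ledger$points_sent <- rowSums(ledger$points)
  ledger$points_received <- colSums(ledger$points)
  ledger$final_payoffs <- ledger$stage1_payoffs -
    cfg$sender_cost * ledger$points_sent -
    cfg$target_cost * ledger$points_received
  ledger
}

#' Validate a round's actions against the phase rules
#'
#' Checks contributions, punishment points and messages against the game
#' bounds and against what the current phase permits (no punishment points
#' outside instrumented rounds or in the message treatment; no messages in
#' the punishment treatment). Violations are returned, not raised, so the
#' caller decides how to react.
#'
#' @param actions A list with elements `contributions` (integer vector),
#'   `points` (square matrix, optional) and `messages` (list of
#'   [norm_message()], optional).
#' @param phase A phase as returned by [treatment_phase()].
#' @param cfg A [game_config()].
#' @return A tibble with columns `member`, `type`
#'   (`"range"`/`"phase"`/`"structure"`) and `message`; zero rows when every
#'   action is legal.
#' @examples
#' cfg <- simulation_config(replications = 1, n_groups = 1)
#' ph <- treatment_phase("punishment", 5, cfg)
#' pts <- matrix(0L, 4, 4); pts[1, 2] <- 2L
#' validate_round(list(contributions = c(0, 0, 0, 0), points = pts), ph)
#' @export
validate_round <- function(actions, phase, cfg = game_config()) {
  v <- list()
  add <- function(member, type, msg) {
    v[[length(v) + 1]] <<- tibble::tibble(member = as.integer(member), type = type, message = msg)
  }
  n <- cfg$group_size
  contrib <- actions$contributions
  if (is.null(contrib) || length(contrib) != n) {
    add(NA, "structure", sprintf("expected contributions for all %d members", n))
  } else {
    bad <- which(is.na(contrib) | contrib < 0 | contrib > cfg$endowment |
                   contrib != round(contrib))
    for (m in bad) {
      add(m, "range", sprintf("contribution %s outside the integer range [0, %d]",
                              format(contrib[m]), cfg$endowment))
    }
  }
  points <- actions$points
  if (!is.null(points) && any(points != 0)) {
    if (!phase$punish_on) {
      senders <- which(rowSums(points != 0) > 0)
      for (m in senders) add(m, "phase", "punishment points assigned while punishment is disabled")
    }
    over <- which(points > cfg$max_points, arr.ind = TRUE)
    for (k in seq_len(nrow(over))) {
      add(over[k, 1], "range", sprintf("more than %d points assigned to one target", cfg$max_points))
    }
    self <- which(diag(points) != 0)
    for (m in self) add(m, "range", "self-punishment is not allowed")
    if (any(is.na(points) | points < 0 | points != round(points))) {
      add(NA, "range", "punishment points must be non-negative integers")
    }
  }
  messages <- actions$messages %||% list()
  for (msg in messages) {
    if (!inherits(msg, "norm_message")) {
      add(NA, "structure", "messages must be norm_message() objects")
      next
    }
    if (!phase$msg_on) add(msg$sender, "phase", "message sent while messages are disabled")
    if (msg$demanded_amount < 0 || msg$demanded_amount > cfg$endowment) {
      add(msg$sender, "range", sprintf("demanded amount outside [0, %d]", cfg$endowment))
    }
  }
  if (length(v) == 0) {
    tibble::tibble(member = integer(), type = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' A normative message
#'
#' The costless message of the message and sanction treatments: "One should
#' contribute X", justified by one of three reasons — the joint benefit
#' (`"JOINT_BENEFIT"`), a sense of duty (`"DUTY"`), or the threat of
#' consequences (`"THREAT"`).
#'
#' @param sender Member id of the sender.
#' @param demanded_amount The demanded contribution X, an integer ECU amount
#'   within the contribution domain.
#' @param reason One of `"JOINT_BENEFIT"`, `"DUTY"`, `"THREAT"` (options
#'   1, 2, 3 on the message menu).
#' @return An object of class `norm_message`.
#' @export
norm_message <- function(sender, demanded_amount,
                         reason = c("JOINT_BENEFIT", "DUTY", "THREAT")) {
  reason <- match.arg(reason)
  if (is.na(demanded_amount) || demanded_amount != round(demanded_amount)) {
    abort("`demanded_amount` must be an integer ECU amount")
  }
  structure(list(sender = as.integer(sender),
                 demanded_amount = as.integer(demanded_amount),
                 reason = reason),
            class = "norm_message")
}

#' Settle an experiment into currency
#'
#' Converts the accumulated final payoffs of a sequence of rounds, plus the
#' show-up payment, into currency: `(show_up + sum(final)) / exchange_rate`
#' per member. Per-round payoffs may be negative; settlement never clips.
#'
#' @param ledgers List of [round_ledger()] objects with punishment applied.
#' @param cfg A [game_config()].
#' @return Numeric vector of currency amounts, one per member.
#' @examples
#' settle_experiment(list(), game_config())  # show-up only: 5 per member
#' @export
settle_experiment <- function(ledgers, cfg = game_config()) {
  total <- rep(0, cfg$group_size)
  for (led in ledgers) {
    if (!inherits(led, "round_ledger")) abort("`ledgers` must contain round_ledger() objects")
    if (anyNA(led$final_payoffs)) {
      abort(sprintf("round %d is incomplete: apply_punishment() has not been run", led$round))
    }
    total <- total + led$final_payoffs
  }
  (cfg$show_up + total) / cfg$exchange_rate
}

#' @export
print.round_ledger <- function(x, ...) {
  cat(sprintf("<round_ledger> round %d\n", x$round))
  cat("  contributions:", paste(x$contributions, collapse = " "), "\n")
  if (!anyNA(x$final_payoffs)) {
    cat("  final payoffs:", paste(format(x$final_payoffs), collapse = " "), "\n")
  } else {
    cat("  stage-1 payoffs:", paste(format(x$stage1_payoffs), collapse = " "),
        "(punishment not yet applied)\n")
  }
  invisible(x)
}
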