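w <- salience_weights()
par <- agent_params()

test_that("salience update matches hand arithmetic with the default weights", {
  # no information, no forgetting
  expect_equal(update_salience(0.6, cue_vector(), w, forgetting_prob = 0), 0.6)
  # clamp at the upper bound
  expect_equal(update_salience(1, cue_vector(own_compliance = 1, observed_compliance = 3,
                                             messages_received = 2), w, 0.3), 1)
  # 0.5 + (3 * 0.33 + 2 * 0.99) / 12, no decay because messages were observed
  expect_equal(
    update_salience(0.5, cue_vector(observed_compliance = 3, messages_received = 2), w, 0.3),
    0.7475
  )
})

test_that("forgetting fades salience only in rounds without norm-signalling cues", {
  # behavioural cues alone do not block the decay: 0.3 * 0.05 on top of the cue sum
  no_signal <- cue_vector(own_violation = 1, observed_violation = 3)
  base <- (-0.99 - 3 * 0.33) / 12
  expect_equal(update_salience(0.5, no_signal, w, forgetting_prob = 0.3), 0.5 + base - 0.015)
  with_signal <- cue_vector(own_violation = 1, observed_violation = 3,
                            punishments_observed = 1)
  expect_equal(update_salience(0.5, with_signal, w, forgetting_prob = 0.3),
               0.5 + (-0.99 - 3 * 0.33 + 0.33) / 12)
  expect_error(update_salience(0.5, c(own_compliance = -1), w), "non-negative|named")
})

test_that("a sanction observation moves salience up at least as much as a bare punishment", {
  expect_gte(w$sanctions_observed, w$punishments_observed)
  s_pun <- update_salience(0.5, cue_vector(punishments_observed = 1), w, 0)
  s_sanc <- update_salience(0.5, cue_vector(sanctions_observed = 1), w, 0)
  expect_gte(s_sanc, s_pun)
  expect_gt(s_sanc, 0.5)
})

test_that("winner-stay losers-change moves the drive by alpha * |dPayoff| / scale", {
  # zero improvement, zero step
  expect_equal(update_individual_drive(0.4, "C", 25, 25, 0.1, 32), 0.4)
  # defection that paid off pulls the drive toward defection
  expect_equal(update_individual_drive(0.5, "D", 32, 0, learning_rate = 0.2,
                                       payoff_scale = 32), 0.3)
  # symmetric: the same improvement after cooperating pulls toward cooperation
  expect_equal(update_individual_drive(0.5, "C", 32, 0, learning_rate = 0.2,
                                       payoff_scale = 32), 0.7)
  # a loss after defecting pushes away from defection
  expect_equal(update_individual_drive(0.5, "D", 0, 32, learning_rate = 0.2,
                                       payoff_scale = 32), 0.7)
  # clamp at the lower bound
  expect_equal(update_individual_drive(0, "D", 32, 0, 0.1, 32), 0)
  expect_error(update_individual_drive(0.5, "D", 1, 0, learning_rate = 0), "learning_rate")
})

test_that("cooperation probability is the convex combination of the drives", {
  expect_equal(cooperation_probability(1, 1, par), 1)
  expect_equal(cooperation_probability(0, 0, par), 0)
  expect_equal(cooperation_probability(0.4, 0.8, par), 0.6)
  # wN = 0: pure payoff learner; wI = 0: salience only
  expect_equal(cooperation_probability(0.37, 0.9, agent_params(1, 0)), 0.37)
  expect_equal(cooperation_probability(0.9, 0.37, agent_params(0, 1)), 0.37)
})

test_that("normative drive and message probability are identity maps of salience", {
  for (s in c(0, 0.25, 0.37, 1)) {
    expect_equal(normative_drive(s), s)
    expect_equal(message_probability(s), s)
  }
  expect_error(normative_drive(1.2), "\\[0, 1\\]")
})

test_that("punishment probability anchors at P0 and decreases in the defector count", {
  expect_equal(punishment_probability(0, par, 4), 0)
  expect_equal(punishment_probability(1, par, 4), 0.5)
  expect_equal(punishment_probability(2, par, 4), 0.5 * (1 - 1 / 3))
  expect_equal(punishment_probability(3, par, 4), 1 / 6)
  p <- punishment_probability(1:3, par, 4)
  expect_true(all(diff(p) < 0))
  expect_error(punishment_probability(4, par, 4), "0\\.\\.3")
})

test_that("punishment intensity is binary and escalates for repeat offenders", {
  expect_equal(choose_intensity(TRUE, FALSE, par), 5L)
  expect_equal(choose_intensity(TRUE, TRUE, par), 10L)
  expect_error(choose_intensity(FALSE, FALSE, par), "defecting target")
  # both intensities cost the target more than the net cost of cooperating
  g <- game_config()
  net_cost_coop <- g$endowment * (1 - g$mpcr)
  expect_gt(g$target_cost * par$low_points, net_cost_coop)
  expect_gt(g$target_cost * par$high_points, net_cost_coop)
})

test_that("drives and salience stay in [0,1] under fuzzed cue and payoff streams", {
  set.seed(202)
  s <- runif(1)
  d <- runif(1)
  for (i in 1:2000) {
    cues <- cue_vector(
      own_compliance = sample(0:1, 1), own_violation = sample(0:1, 1),
      observed_compliance = sample(0:3, 1), observed_violation = sample(0:3, 1),
      punishments_observed = sample(0:6, 1), sanctions_observed = sample(0:6, 1),
      messages_received = sample(0:3, 1), unpunished_violations = sample(0:3, 1)
    )
    s <- update_salience(s, cues, w, forgetting_prob = runif(1))
    expect_true(s >= 0 && s <= 1)
    d <- update_individual_drive(d, sample(c("C", "D"), 1), runif(1, -90, 50),
                                 runif(1, -90, 50), learning_rate = runif(1, 0.01, 1))
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("cooperation probability is monotone in each drive", {
  set.seed(303)
  for (i in 1:200) {
    id <- sort(runif(2)); nd <- sort(runif(2))
    expect_lte(cooperation_probability(id[1], nd[1], par),
               cooperation_probability(id[2], nd[1], par))
    expect_lte(cooperation_probability(id[1], nd[1], par),
               cooperation_probability(id[1], nd[2], par))
  }
})

test_that("weight sign structure is enforced", {
  expect_error(salience_weights(own_compliance = -0.1), "non-negative")
  expect_error(salience_weights(unpunished_violations = 0.1), "non-positive")
  expect_error(salience_weights(lambda = 0), "lambda")
  expect_error(agent_params(individual_weight = 0.7, normative_weight = 0.5), "sum to 1")
  expect_error(agent_params(low_points = 7, high_points = 7), "low_points")
  # the cost relation ties agents to the game: too-weak low intensity is rejected
  expect_error(simulation_config(agents = agent_params(low_points = 2, high_points = 10)),
               "net cost")
})
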