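cfg <- game_config()

test_that("stage-1 payoffs follow the public-good formula", {
  expect_equal(stage1_payoffs(c(0, 0, 0, 0), cfg), c(20, 20, 20, 20))
  expect_equal(stage1_payoffs(c(20, 20, 20, 20), cfg), c(32, 32, 32, 32))
  # the free-rider keeps the endowment and still earns from the group account
  expect_equal(stage1_payoffs(c(0, 20, 20, 20), cfg), c(44, 24, 24, 24))
})

test_that("stage-1 payoffs validate contributions and name the offender", {
  expect_error(stage1_payoffs(c(0, 0, 0, 21), cfg), "member 4")
  expect_error(stage1_payoffs(c(0, 0.5, 0, 0), cfg), "member 2")
  expect_error(stage1_payoffs(c(0, 0, 0), cfg), "expected 4")
})

test_that("group payoff conservation holds exactly on random contribution vectors", {
  set.seed(101)
  for (i in 1:1000) {
    c_vec <- sample(0:20, 4, replace = TRUE)
    e <- stage1_payoffs(c_vec, cfg)
    expect_equal(sum(e), 4 * 20 + (4 * 0.4 - 1) * sum(c_vec), tolerance = 1e-12)
  }
})

test_that("punishment accounting charges 1 to the sender and 3 to the target", {
  led <- apply_punishment(round_ledger(12, c(20, 20, 20, 20), cfg = cfg))
  expect_equal(led$final_payoffs, c(32, 32, 32, 32))  # no punishment

  pts <- matrix(0L, 4, 4); pts[1, 2] <- 2L
  led <- apply_punishment(round_ledger(12, c(20, 20, 20, 20), points = pts, cfg = cfg))
  expect_equal(led$points_sent, c(2, 0, 0, 0))
  expect_equal(led$points_received, c(0, 2, 0, 0))
  expect_equal(led$final_payoffs, c(30, 26, 32, 32))

  pts <- matrix(0L, 4, 4); pts[1, 2:4] <- 10L  # cap case: 10 to each other member
  led <- apply_punishment(round_ledger(12, c(20, 20, 20, 20), points = pts, cfg = cfg))
  expect_equal(led$points_sent[1], 30)
  expect_equal(led$final_payoffs[1], led$stage1_payoffs[1] - 30)
})

test_that("punishment destroys exactly (sender_cost + target_cost) * points of group ECU", {
  set.seed(7)
  for (i in 1:200) {
    pts <- matrix(sample(0:10, 16, replace = TRUE), 4, 4)
    diag(pts) <- 0L
    led <- apply_punishment(round_ledger(11, sample(0:20, 4, TRUE), points = pts, cfg = cfg))
    expect_equal(sum(led$stage1_payoffs) - sum(led$final_payoffs), 4 * sum(pts))
    expect_true(sum(led$final_payoffs) <= sum(led$stage1_payoffs))
  }
})

test_that("punishment accounting is equivariant under permutation of members", {
  pts <- matrix(0L, 4, 4); pts[1, 2] <- 3L; pts[4, 2] <- 7L; pts[2, 3] <- 1L
  c_vec <- c(0L, 20L, 5L, 10L)
  led <- apply_punishment(round_ledger(11, c_vec, points = pts, cfg = cfg))
  perm <- c(3, 1, 4, 2)
  led_p <- apply_punishment(round_ledger(11, c_vec[perm], points = pts[perm, perm], cfg = cfg))
  expect_equal(led_p$final_payoffs, led$final_payoffs[perm])
})

test_that("point matrices violating the cap or the zero diagonal are rejected", {
  pts <- matrix(0L, 4, 4); pts[1, 2] <- 11L
  expect_error(round_ledger(11, rep(0L, 4), points = pts, cfg = cfg), "cap")
  pts <- matrix(0L, 4, 4); pts[2, 2] <- 1L
  expect_error(round_ledger(11, rep(0L, 4), points = pts, cfg = cfg), "Self-punishment",
               ignore.case = TRUE)
})

test_that("validate_round flags phase and range violations but not legal actions", {
  scfg <- simulation_config(n_groups = 1, replications = 1)
  pts <- matrix(0L, 4, 4); pts[1, 2] <- 2L

  # punishment while instruments are off (baseline round 5)
  v <- validate_round(list(contributions = rep(0L, 4), points = pts),
                      treatment_phase("punishment", 5, scfg), cfg)
  expect_equal(nrow(v), 1)
  expect_equal(v$type, "phase")

  # a duty message in an instrumented sanction round is legal
  v <- validate_round(
    list(contributions = rep(0L, 4), points = pts,
         messages = list(norm_message(2, 15, "DUTY"))),
    treatment_phase("sanction", 12, scfg), cfg
  )
  expect_equal(nrow(v), 0)

  # message in the punishment treatment is a phase violation
  v <- validate_round(list(contributions = rep(0L, 4),
                           messages = list(norm_message(1, 10))),
                      treatment_phase("punishment", 12, scfg), cfg)
  expect_equal(v$type, "phase")

  # out-of-range contribution
  v <- validate_round(list(contributions = c(21L, 0L, 0L, 0L)),
                      treatment_phase("message", 1, scfg), cfg)
  expect_equal(v$type, "range")
  expect_equal(v$member, 1L)
})

test_that("settlement converts accumulated ECU at the exchange rate and never clips", {
  expect_equal(settle_experiment(list(), cfg), rep(5, 4))  # show-up only

  lednc <- apply_punishment(round_ledger(1, rep(0L, 4), cfg = cfg))
  expect_equal(settle_experiment(rep(list(lednc), 30), cfg), rep(20, 4))

  pts <- matrix(0L, 4, 4); pts[2, 1] <- 10L  # member 1 ends the round at -10
  led <- apply_punishment(round_ledger(1, rep(0L, 4), points = pts, cfg = cfg))
  expect_equal(led$final_payoffs[1], -10)
  expect_equal(settle_experiment(list(led), cfg)[1], 4.75)

  raw <- round_ledger(1, rep(0L, 4), cfg = cfg)  # punishment never applied
  expect_error(settle_experiment(list(raw), cfg), "incomplete")
})

test_that("the social-dilemma condition and positivity are enforced", {
  expect_error(game_config(mpcr = 1.5), "social-dilemma")
  expect_error(game_config(mpcr = 0.2, group_size = 4), "social-dilemma")
  expect_error(game_config(max_points = 0), "positive")
})
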