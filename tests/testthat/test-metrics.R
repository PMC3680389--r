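test_that("block means are computed group-first and read fixture cells verbatim", {
  bm <- block_means(human_baseline(), blocks = "16-20")
  expect_equal(bm$mean_contribution[match(c("message", "punishment", "sanction"),
                                          bm$treatment)],
               c(9.90, 10.65, 14.46))

  # two groups with means 4 and 6 average to 5, whatever their sizes imply
  rounds <- tibble::tibble(
    treatment = factor("punishment"), replication = 1L,
    group = rep(1:2, each = 4), round = rep(1:2, 4),
    contribution = c(rep(4, 4), c(0, 12, 6, 6)), final_payoff = 0
  )
  bm <- block_means(rounds, blocks = "1-2")
  expect_equal(bm$mean_contribution, 5)
  expect_error(block_means(rounds, blocks = "5-6"), "no rounds")
})

test_that("an all-cooperate panel has block mean 20 and all-defect earns 20/round", {
  cfg <- simulation_config(agents = agent_params(init_drive = 1, init_salience = 1),
                           n_groups = 1, replications = 1, treatments = "sanction")
  sim <- run_experiment(cfg)
  expect_equal(block_means(sim, "1-10")$mean_contribution, 20)
  # full cooperation without punishment: stage-1 payoff 32 per member per round
  expect_equal(earnings_summary(sim, "1-10")$mean_earnings, 32)

  cfg0 <- simulation_config(agents = agent_params(init_drive = 0, init_salience = 0),
                            n_groups = 1, replications = 1, treatments = "punishment")
  sim0 <- run_experiment(cfg0)
  expect_equal(earnings_summary(sim0, "1-10")$mean_earnings, 20)
})

make_sim_stub <- function(acts, n_groups = 1, replications = 1) {
  cfg <- simulation_config(n_groups = n_groups, replications = replications,
                           treatments = "punishment")
  structure(list(rounds = tibble::tibble(), acts = acts, config = cfg),
            class = "norm_sim")
}

test_that("punishment frequency counts used sender-target opportunities", {
  acts <- tibble::tibble(treatment = factor("punishment"), replication = 1L,
                         group = 1L, round = 11L, sender = 1L, target = 2L,
                         points = 5L)
  pf <- punishment_frequency(make_sim_stub(acts), rounds = 11)
  expect_equal(pf$n_opportunities, 12)  # 4 * 3 ordered pairs in one round
  expect_equal(pf$frequency, 1 / 12)

  pf0 <- punishment_frequency(make_sim_stub(acts[0, ]), rounds = 11)
  expect_equal(pf0$frequency, 0)
  expect_error(punishment_frequency(make_sim_stub(acts), rounds = integer(0)), "empty")
})

test_that("punishment intensity averages nonzero acts and is NA when undefined", {
  acts <- tibble::tibble(treatment = factor("punishment"),
                         replication = 1L, group = 1L, round = c(11L, 12L),
                         sender = 1L, target = 2L, points = c(2L, 4L))
  pi_ <- punishment_intensity(make_sim_stub(acts), rounds = 11:20)
  expect_equal(pi_$intensity, 3)
  single <- punishment_intensity(make_sim_stub(acts[2, ]), rounds = 11:20)
  expect_equal(single$intensity, 4)
  none <- punishment_intensity(make_sim_stub(acts[0, ]), rounds = 11:20)
  expect_true(is.na(none$intensity))
})

test_that("uniform low-point acts give intensity exactly low_points at any frequency", {
  acts <- tibble::tibble(treatment = factor("punishment"), replication = 1L,
                         group = 1L, round = rep(11:15, each = 2),
                         sender = rep(1:2, 5), target = rep(3:4, 5), points = 5L)
  stub <- make_sim_stub(acts)
  expect_equal(punishment_intensity(stub, 11:20)$intensity, 5)
  expect_equal(punishment_frequency(stub, 11:20)$frequency, 10 / 120)
})

test_that("percent excess rounds to the nearest integer percent", {
  expect_identical(percent_excess(14.46, 10.65), 36L)
  expect_identical(percent_excess(9.08, 3.75), 142L)
  expect_identical(percent_excess(7, 7), 0L)
  expect_error(percent_excess(1, 0), "positive")
})

test_that("forward and reverse percent excess satisfy the pre-rounding identity", {
  set.seed(44)
  for (i in 1:100) {
    a <- runif(1, 0.1, 30); b <- runif(1, 0.1, 30)
    fwd <- 100 * (a - b) / b
    rev <- 100 * (b - a) / a
    expect_equal((1 + fwd / 100) * (1 + rev / 100), 1, tolerance = 1e-12)
  }
})

test_that("replication-level aggregates agree with direct panel computation", {
  sim <- small_sim(seed = 23)
  rm <- replication_means(sim, 11:20)
  direct <- sim$rounds |>
    dplyr::filter(round %in% 11:20) |>
    dplyr::group_by(treatment, replication) |>
    dplyr::summarise(m = mean(contribution), .groups = "drop")
  # groups are balanced, so the two-stage and pooled means coincide
  expect_equal(rm$mean_value, direct$m)
  rf <- replication_frequencies(sim, 11:20)
  expect_equal(sum(rf$n_acts), nrow(dplyr::filter(sim$acts, round %in% 11:20)))
  expect_true(all(rf$frequency[rf$treatment == "message"] == 0))
})
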