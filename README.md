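# normgame

Why does material punishment sometimes fail to sustain cooperation, and
why does it work so much better when it carries an explicit message about
what the norm *is*? `normgame` is an R package for studying that question
in the classic repeated public-goods game with costly punishment. It
provides:

* an exact accounting engine for the laboratory game — stage-1 payoffs
  `E_i = e − c_i + m · Σ c_j` (endowment `e = 20` ECU, MPCR `m = 0.4`,
  groups of 4), punishment points at a 1:3 sender:target cost, normative
  messages, validation, and ECU→currency settlement;
* an agent-based model with a *norm psychology*: agents cooperate with
  probability `P(C) = w_I·ID + w_N·ND`, where the individual drive ID
  learns from payoffs by a winner-stay losers-change rule and the
  normative drive ND tracks **norm salience** — a `[0,1]` scalar updated
  every round from observed compliance, violations, punishments, sanctions
  (punishment + message) and messages;
* a seeded, replicated experiment runner over the three treatments
  (punishment-only, message-only, sanction) with the 1–10 / 11–20 / 21–30
  block schedule, returning tidy tibbles;
* the measurement layer of this experimental design — block means,
  punishment frequency (share of sender→target opportunities used) and
  intensity (points per act, zeros excluded), net earnings, percent-excess
  comparisons — plus group-level Kruskal–Wallis, Mann–Whitney and Wilcoxon
  signed-rank tests with exact small-sample branches;
* the published human block means as an immutable fixture table, and a
  qualitative (ordering-based) comparison of simulated panels against
  them.

Everything is tibble-in/tibble-out and pipe-friendly; simulation results
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Run the reference experiment — 100 replications of 12 groups for each of
the three treatments, fully determined by the master seed:

```r
library(normgame)

cfg <- simulation_config(seed = 1)   # defaults: wI = wN = 0.5, P0 = 0.5, phi = 0.3
sim <- run_experiment(cfg)
sim
#> <norm_sim>
#>   treatments: punishment, message, sanction
#>   12 groups x 100 replications x 30 rounds (432000 agent-rounds), seed 1
#>   49079 punishing acts recorded

block_means(sim, c("1-10", "11-20", "21-30"))
#> # A tibble: 9 × 3
#>   treatment  block mean_contribution
#>   <fct>      <chr>             <dbl>
#> 1 punishment 1-10               8.34
#> 2 message    1-10               8.16
#> 3 sanction   1-10               8.44
#> 4 punishment 11-20              6.65
#> 5 message    11-20              5.12
#> 6 sanction   11-20              7.87
#> 7 punishment 21-30              6.07
#> 8 message    21-30              3.24
#> 9 sanction   21-30              8.09
```

The treatment structure is the point: the three arms are indistinguishable
in the baseline block (rounds 1–10, instruments off, contributions
declining); once instruments switch on, the sanction arm sustains the
highest cooperation and keeps it after the instruments are withdrawn
(rounds 21–30), while message-only cooperation collapses. Punishment is
also *used less* when it carries a message:

```r
punishment_frequency(sim, 11:20)
#> # A tibble: 3 × 4
#>   treatment  n_acts n_opportunities frequency
#>   <fct>       <int>           <dbl>     <dbl>
#> 1 punishment  25236          144000     0.175
#> 2 message         0          144000     0
#> 3 sanction    23843          144000     0.166

compare_to_fixtures(sim)$pass   # 8 ordering checks against the human data
#> [1] TRUE TRUE TRUE TRUE TRUE TRUE TRUE TRUE
```

On the reported human block means themselves, the percent-excess
arithmetic of the sanction over the punishment treatment:

```r
fx <- human_baseline()
percent_excess(14.46, 10.65)  # rounds 16-20
#> [1] 36
percent_excess(9.08, 3.75)    # rounds 21-30
#> [1] 142
```

i.e. sanctioned groups contribute 36% more in late instrumented rounds and
142% more after instruments are removed.

A thin command-line front end ships in `inst/scripts/normgame`
(`simulate`, `analyze`, `compare-fixtures`, `fixtures` verbs); the methods
vignette (`vignettes/norm-psychology-model.Rmd`) documents the model, its
parameters and its limitations.

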