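---
title: "Norm psychology in a public-goods game: the model behind normgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norm psychology in a public-goods game: the model behind normgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normgame)
library(dplyr)
```

## The game

Four members play a repeated linear public-goods game for 30 rounds. Each
round, member $i$ splits an endowment of 20 ECU between a private account
and a group account, choosing an integer contribution $c_i \in [0, 20]$.
The group account pays a marginal per-capita return (MPCR) of 0.4, so the
stage-1 payoff is

$$E_i = 20 - c_i + 0.4 \sum_j c_j .$$

Because $\text{MPCR} < 1 < \text{MPCR} \times 4$, contributing nothing is
individually dominant while full contribution maximizes the group payoff —
the standard social dilemma. In rounds 11–20 ("instrumented" rounds) the
treatments differ:

* **punishment** — after contributions are revealed, each member may assign
  0–10 punishment points to each other member; a point costs the sender
  1 ECU and the target 3 ECU;
* **message** — no material punishment, but each member may send a costless
  normative message ("one should contribute X, because …", with one of
  three reasons: joint benefit, duty, or threat);
* **sanction** — both instruments at once: punishing *and* telling the
  target what the norm is.

Rounds 1–10 and 21–30 are identical baseline blocks in every treatment.
Final payoffs, $E_i - p_i - 3\,p_r$ with $p_i$ points sent and $p_r$ points
received, may be negative; accumulated ECU plus a 200 ECU show-up payment
convert to currency at 40 ECU per unit at the end
(`settle_experiment()`).

The engine (`stage1_payoffs()`, `round_ledger()`, `apply_punishment()`,
`validate_round()`) does this accounting exactly, and two conservation
identities are enforced by tests: $\sum_i E_i = 80 + 0.6 \sum_j c_j$, and
punishment destroys exactly $(1+3)\times$ the points assigned — it can
never create ECU.

## The agents

Simulated agents make a binary choice: cooperate (contribute the full
endowment, 20 ECU by default) or defect (contribute nothing). The
cooperation probability combines two motives,

$$P(C) = w_I \cdot \mathrm{ID} + w_N \cdot \mathrm{ND},$$

a convex combination of the **individual drive** ID (payoff learning) and
the **normative drive** ND (norm salience), both in $[0,1]$. The reference
parameterization is $w_I = w_N = 0.5$, initial punishment probability
$P_0 = 0.5$, forgetting probability $\phi = 0.3$.

### Individual drive: winner-stay losers-change

ID is the learned propensity to cooperate. After each round the agent
compares its final payoff with the previous round's. If the payoff did not
drop, ID moves *toward* the propensity of the action just taken (toward 1
after C, toward 0 after D); if it dropped, ID moves *away* from it. The
step is $\alpha \, |\Delta \text{payoff}| / s$ with learning rate
$\alpha = 0.1$ and scale $s = \text{endowment} \times \text{group size}
\times \text{MPCR} = 32$ (the maximal stage-1 swing), chosen so one round
moves the drive by far less than 1. An unchanged payoff moves nothing, and
the result is clamped to $[0,1]$. This is why material punishment works on
the instrumental channel: a punished defector just experienced a payoff
drop after defecting, and its ID rises.

### Normative drive: norm salience

Each agent tracks a **norm salience** value in $[0,1]$ — how prominent the
cooperation norm currently appears — and ND is read off it directly
(identity map; `normative_drive()`). Salience is updated every round from
the cues the agent observed:

| cue | default weight |
|---|---|
| own compliance | $+0.99$ |
| own violation | $-0.99$ |
| observed compliance (per complying other) | $+0.33$ |
| observed violation (per defecting other) | $-0.33$ |
| punishment observed (per bare punishing act) | $+0.33$ |
| sanction observed (per punishing act whose sender also messaged) | $+0.99$ |
| message received (per pure message) | $+0.99$ |
| unpunished violation (per defector receiving no points) | $-0.66$ |

The update adds the weighted cue sum divided by $\lambda = 12$ (three times
the group size) and clamps to $[0,1]$. The signs are structural: complying
and norm-signalling cues cannot lower salience, violations cannot raise it,
and a sanction — punishment carrying explicit normative content — is a
strictly stronger signal than bare punishment ($0.99$ vs $0.33$). The
numeric values themselves are package defaults chosen to respect that
ordering; they are fully configurable through `salience_weights()`, so a
different calibration can be dropped in without touching code.

Three modelling choices here were genuinely open and deserve a record:

* **Forgetting.** A norm that is never signalled fades. In rounds where an
  agent observes *no* norm-signalling cue (no punishment, sanction or
  message), salience additionally decays by $\phi \times 0.05$. We
  deliberately tie the decay to the absence of *signalling* cues rather
  than the absence of all cues: in any played round the agent always has
  its own compliance/violation cue, so an all-cues-empty trigger would
  never fire and $\phi$ would be inert. A Bernoulli variant (full 0.05
  step with probability $\phi$) is switchable via
  `agent_params(forgetting_model = "bernoulli")`.
* **When does a violation count as "unpunished"?** Only from the first
  instrumented round onward. The cue means "a violation that the group
  visibly let pass", which presupposes that norm enforcement is on the
  table. Counting it from round 1 would drive salience to the floor before
  any instrument exists, so that by round 11 no agent would send messages
  at all (message probability tracks salience) — contradicting the intended
  dynamics in which the message and sanction treatments *start* block 2 at
  similar levels and diverge later. With the gating, baseline decline is
  carried by the mild behavioural cues plus forgetting, and block 3 (after
  instruments are withdrawn) still erodes salience through unpunished
  violations — which is exactly the mechanism that makes cooperation decay
  after round 20.
* **Message content.** Human subjects overwhelmingly demand full
  contribution with the joint-benefit reason; since the agents' choice is
  binary, the simulated message is a bare pro-cooperation invocation
  (amount = the cooperate contribution, reason fixed to `JOINT_BENEFIT`).
  The data model (`norm_message()`) still carries all three reasons and an
  arbitrary demanded amount, for hand-built and replayed games.

### Punishing and messaging

After contributions are revealed in an instrumented round, each agent
considers every defecting *other* member. With $d$ such defectors, each is
punished independently with probability

$$P(\text{punish} \mid d) = P_0 \left(1 - \frac{d-1}{n-1}\right),$$

which anchors at $P_0$ for a lone defector and declines as defection
spreads (when "everyone does it", the norm looks weak and enforcement
wanes); nobody punishes when nobody defects. Intensity is binary: 5 points
for a first-time defector, 10 (the cap) for one who also defected in the
immediately preceding round. Both satisfy the cost constraint that being
punished must hurt more than cooperating would have: $3 \times 5 = 15 >
20 \times (1 - 0.4) = 12$; `simulation_config()` refuses parameter
combinations that break this. Whether the high/low choice should instead
depend on salience or be random is not determined by the design we follow;
escalation on repeat offence is the package's default and is the only part
of the punishment policy that uses individual histories.

Message sending is one draw per agent per instrumented round with
probability equal to current salience (`message_probability()`, identity
map — the simplest monotone reading). This closes the central feedback
loop: messages raise observers' salience, higher salience produces more
messages and more cooperation, and material punishment protects the loop
from erosion by making violations costly *and* rarer.

## The experiment runner

`run_experiment()` plays all configured treatments (default: the three of
the design; a `"none"` control arm is also supported for ablations) for
`replications` independent replications of `n_groups` fixed groups. Every
(treatment, replication, group) triple runs on its own RNG substream whose
seed is derived from the master seed by a Lehmer-style hash, so results are
bit-reproducible and independent of execution order; the determinism
contract (identical master seed, byte-identical exported CSV) is tested.
The per-round event order is: cooperation draws, contribution revelation,
punishment and message draws, payoff accounting, cue construction, salience
and drive updates.

The default problem size — 100 replications × 12 groups × 3 treatments ×
30 rounds × 4 agents (432,000 agent-rounds, about 15 s on one core) — is
chosen so that replication-level Monte-Carlo error is small relative to the
treatment effects; the test suite and the acceptance script both run it in
full.

## Measurement and statistics

`block_means()` and `earnings_summary()` aggregate group-first: each
(replication, group) contributes one mean and those independent group
means are averaged, mirroring the group-level unit of the nonparametric
battery. `punishment_frequency()` is the share of ordered sender–target
opportunities ($4 \times 3$ per group-round) with positive points;
`punishment_intensity()` is the mean points per punishing act with zero
acts *excluded* — an intensity over no acts is reported as `NA`, never 0.

The test battery (`kruskal_wallis()`, `mann_whitney()`,
`wilcoxon_signed_rank()`) wraps the standard R implementations with the
conventions fixed: midranks with tie-corrected variance, two-sided
p-values by default, exact null distributions for small samples (combined
$n \le 10$ tie-free for Mann–Whitney; up to 12 pairs for the signed-rank
test, where the exact branch enumerates all $2^n$ sign patterns itself so
that tied absolute differences — e.g. constant shifts — are still exact).
Every statistic is cross-checked in the test suite against brute-force
enumeration oracles on all small sample shapes.

## What the simulation does and does not emulate

The generator reproduces the *design* of the laboratory experiment — group
size, blocks, instruments, payoff technology — and is intended to
reproduce its qualitative treatment structure: sanctioning yields higher
and more persistent cooperation than bare punishment or bare messaging,
punishment is used less often when it carries normative content, message
cooperation decays within block 2, and contributions decline within the
baseline block. These orderings, with Mann–Whitney confirmation at the
replication level, are exactly what `compare_to_fixtures()` and the
acceptance checks verify.

It does **not** emulate: graded contributions (agents are binary, so
simulated contribution means are comparable to human token means only in
ordering, not level); heterogeneous demanded amounts or message reasons;
subject-pool effects; or the human tendency to resist the post-instrument
decline in rounds 21–30 — simulated cooperation decays faster there than
human cooperation does. Consequently, a passing suite supports the
mechanism story (norm salience as the mediator of the sanction advantage),
not any numeric claim about human levels, p-values or earnings. The
reported human block means ship as an immutable fixture table
(`human_baseline()`) and are compared against simulations by ordering
only.

## Numerical and degenerate-input conventions

* Salience and both drives are hard-clamped to $[0,1]$ after every update;
  fuzz tests exercise 10,000 random cue/payoff streams.
* Equal payoffs count as "winner" in the WSLS rule but produce a zero step,
  so the tie-break has no numerical effect.
* `percent_excess()` rounds to the nearest integer percent; the forward and
  reverse comparisons satisfy $(1 + a/100)(1 + b'/100) = 1$ before
  rounding.
* Empty scopes error loudly (empty block, no rounds, no opportunities);
  undefined quantities that are legitimately reachable (intensity with no
  acts, signed-rank test with all-zero differences) return explicit
  `NA`/degenerate markers instead.
* All randomness flows through R's RNG seeded per substream; no
  order-dependent floating accumulation enters any decision.

## A small worked ablation

Setting $w_N = 0$ removes the normative channel entirely: cooperation then
depends only on payoff learning, messages become behaviourally inert, and
the sanction treatment collapses onto the punishment treatment (and the
message treatment onto a no-instrument control). The acceptance suite runs
this ablation at full scale; here is a reduced version:

```{r ablation}
abl <- run_experiment(simulation_config(
  agents = agent_params(individual_weight = 1, normative_weight = 0),
  n_groups = 4, replications = 10, seed = 7,
  treatments = c("punishment", "sanction")
))
rm <- replication_means(abl, 11:20)
mann_whitney(rm$mean_value[rm$treatment == "sanction"],
             rm$mean_value[rm$treatment == "punishment"])
```

With the normative weight restored, the same comparison separates sharply
— that contrast is the package's core claim about mechanism.

## Known limitations

* The salience weight table and the drive/salience functional forms are
  package defaults satisfying the documented sign and ordering structure,
  not a calibration against behavioural data; conclusions should be read
  at the level of orderings and mechanisms.
* Punisher identities are recorded in the ledgers (as in the laboratory
  information set) but the default cues use only counts; identity-sensitive
  norm psychology is an extension hook, not a feature.
* No evolutionary dynamics, population turnover, or learning of the weight
  table itself.
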