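Package: normgame
Title: Public-Goods Games with Costly Punishment and Norm-Signalling Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates repeated public-goods games with costly punishment,
    normative messages, and combined sanctions, played by agents whose
    cooperation is driven jointly by payoff learning (a winner-stay
    losers-change individual drive) and a norm-salience mechanism (a
    normative drive updated from observed compliance, violations,
    punishments, sanctions and messages). Provides exact payoff accounting
    for the laboratory game, a seeded replicated experiment runner over the
    punishment, message and sanction treatments, block-level metrics
    (contributions, punishment frequency and intensity, net earnings),
    nonparametric group-level tests, a fixture table of reported human
    block means, and qualitative comparison of simulated panels against
    those fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
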