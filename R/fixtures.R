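#' Reported block means of the human experiment
#'
#' The published block-level mean contributions of the laboratory
#' experiment, by treatment (message, punishment, sanction) and round block
#' (1-10, 16-20, 21-30), with a provenance tag per cell. These fixtures
#' anchor the qualitative comparison of simulated panels
#' ([compare_to_fixtures()]) and the arithmetic percent-excess comparisons
#' ([percent_excess()]).
#'
#' @return A tibble of class `fixture_table` with columns `treatment`,
#'   `block`, `mean_contribution`, `provenance`.
#' @examples
#' human_baseline()
#' @export
human_baseline <- function() {
  path <- system.file("extdata", "human_block_means.csv", package = "normgame",
                      mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  tbl$treatment <- factor(tbl$treatment, levels = c("message", "punishment", "sanction"))
  class(tbl) <- c("fixture_table", class(tbl))
  tbl
}

fixture_cell <- function(fixtures, treatment, block) {
  v <- fixtures$mean_contribution[fixtures$treatment == treatment &
                                    fixtures$block == block]
  if (length(v) != 1) abort(sprintf("fixture table is missing %s / %s", treatment, block))
  v
}

sim_cell <- function(bm, treatment, block) {
  v <- bm$mean_contribution[bm$treatment == treatment & bm$block == block]
  if (length(v) != 1) abort(sprintf("summary is missing %s / %s", treatment, block))
  v
}

#' Qualitative comparison of a simulated panel against the human fixtures
#'
#' The agent model is binary-choice and is claimed to reproduce trends, not
#' levels, so the fixture contract is a set of sign/ordering checks rather
#' than numeric distances: (i) sanction above punishment and above message
#' in blocks 16-20 and 21-30; (ii) contribution decline within the baseline
#' rounds 1-10 (first half vs second half); (iii) punishment frequency
#' higher in the punishment than in the sanction treatment. Checks that
#' need per-round or per-act records (ii, iii) are only reported when `x`
#' is a full `norm_sim` object.
#'
#' @param x A `norm_sim` object, or any block-mean summary with columns
#'   `treatment`, `block`, `mean_contribution` (including the fixture table
#'   itself).
#' @param fixtures A [human_baseline()] fixture table; its own orderings
#'   define the expected directions and are verified as a sanity check.
#' @return A tibble with columns `check`, `description`, `pass`.
#' @examples
#' compare_to_fixtures(human_baseline())
#' @export
compare_to_fixtures <- function(x, fixtures = human_baseline()) {
  for (b in c("16-20", "21-30")) {
    stopifnot(fixture_cell(fixtures, "sanction", b) > fixture_cell(fixtures, "punishment", b),
              fixture_cell(fixtures, "sanction", b) > fixture_cell(fixtures, "message", b))
  }
  is_sim <- inherits(x, "norm_sim")
  bm <- if (is_sim || (is.data.frame(x) && "round" %in% names(x))) {
    block_means(x, blocks = c("16-20", "21-30"))
  } else {
    x
  }
  checks <- list()
  add <- function(check, description, pass) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, description = description, pass = pass
    )
  }
  for (b in c("16-20", "21-30")) {
    for (other in c("punishment", "message")) {
      add(sprintf("sanction_gt_%s_%s", other, gsub("-", "_", b)),
          sprintf("mean contribution, rounds %s: sanction > %s", b, other),
          sim_cell(bm, "sanction", b) > sim_cell(bm, other, b))
    }
  }
  if (is_sim) {
    rt <- x$rounds
    early <- block_means(x, blocks = "1-5")
    late <- block_means(x, blocks = "6-10")
    for (tr in levels(rt$treatment)) {
      if (tr == "none") next
      add(sprintf("decline_1_10_%s", tr),
          sprintf("mean contribution, %s treatment: rounds 1-5 > rounds 6-10", tr),
          sim_cell(early, tr, "1-5") > sim_cell(late, tr, "6-10"))
    }
    if (all(c("punishment", "sanction") %in% levels(rt$treatment))) {
      pf <- punishment_frequency(x)
      add("pf_punishment_gt_sanction",
          "punishment frequency, instrument rounds: punishment > sanction",
          pf$frequency[pf$treatment == "punishment"] >
            pf$frequency[pf$treatment == "sanction"])
    }
  }
  dplyr::bind_rows(checks)
}
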