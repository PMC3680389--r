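# Independent brute-force oracles for the rank tests, used to cross-check
# the package's wrappers on small samples.

# Mann-Whitney U for x relative to y (ties count one half)
oracle_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided p by enumeration of all assignments of the combined
# (tie-free) values to the two samples
oracle_mw_p <- function(x, y) {
  m <- length(x)
  combined <- c(x, y)
  stopifnot(!any(duplicated(combined)))
  u_obs <- oracle_mw_u(x, y)
  picks <- utils::combn(length(combined), m)
  u_all <- apply(picks, 2, function(ix) oracle_mw_u(combined[ix], combined[-ix]))
  if (u_obs > m * (length(y)) / 2) {
    min(1, 2 * mean(u_all >= u_obs))
  } else {
    min(1, 2 * mean(u_all <= u_obs))
  }
}

# Tie-corrected Kruskal-Wallis H from the defining rank formula
oracle_kw_h <- function(samples) {
  values <- unlist(samples)
  n_i <- lengths(samples)
  N <- length(values)
  r <- rank(values)
  grp <- rep(seq_along(samples), n_i)
  rbar <- tapply(r, grp, mean)
  h <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Exact one-sided p for the Wilcoxon signed-rank test by enumeration of all
# 2^n sign patterns on the midranked absolute differences; alternative
# "greater" refers to x - y > 0, evaluated on the positive-rank sum V
oracle_wsr_p_greater <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(v_all >= v_obs)
}

# deterministic mini-simulation used by several test files
small_sim <- function(seed = 11, n_groups = 2, replications = 2,
                      treatments = c("punishment", "message", "sanction")) {
  run_experiment(simulation_config(
    n_groups = n_groups, replications = replications, seed = seed,
    treatments = treatments
  ))
}
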