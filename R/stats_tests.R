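#' Kruskal-Wallis test on two or more groups of group-level values
#'
#' Rank-based one-way comparison of k independent samples (typically one
#' mean per experimental group), with midranks for ties and the standard
#' tie-corrected H statistic; the p-value comes from the chi-square
#' approximation with k - 1 degrees of freedom.
#'
#' @param samples A list of two or more nonempty numeric vectors.
#' @return A one-row tibble: `statistic` (tie-corrected H), `df`, `p_value`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2) {
    abort("`samples` must be a list of at least two groups")
  }
  if (any(vapply(samples, length, integer(1)) == 0)) abort("every sample must be nonempty")
  values <- unlist(samples)
  grp <- factor(rep(seq_along(samples), vapply(samples, length, integer(1))))
  res <- kruskal.test(values, grp)
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value)
}

#' Mann-Whitney U test for two independent samples
#'
#' The U statistic counts pairs `(x_i, y_j)` with `x_i > y_j` (ties count
#' one half). For small tie-free samples (combined n of at most 10) the
#' p-value is exact, from the full null distribution of U; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Nonempty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A one-row tibble: `statistic` (U), `p_value`, `n_x`, `n_y`,
#'   `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  exact <- (length(x) + length(y) <= 10) && !any(duplicated(c(x, y)))
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact, correct = TRUE)
  )
  tibble::tibble(statistic = unname(res$statistic), p_value = res$p.value,
                 n_x = length(x), n_y = length(y), exact = exact)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Pairs with zero difference are dropped; the remaining absolute
#' differences are ranked, and `statistic` reports W, the smaller of the
#' positive- and negative-rank sums (so flipping the sign of every
#' difference leaves it unchanged; `v` is the positive-rank sum that
#' directed alternatives are evaluated on). For at most 12 pairs the
#' p-value is exact, by enumeration of all `2^n` equiprobable sign patterns
#' on the (mid)ranked absolute differences — this covers tied absolute
#' differences such as constant shifts, where `n` pairs shifted by the same
#' amount give a one-sided p of exactly `1 / 2^n`. Beyond 12 pairs the
#' normal approximation with continuity correction is used. When every
#' difference is zero the test is degenerate and all statistics are `NA`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (directions refer to `x - y`).
#' @return A one-row tibble: `statistic` (W), `v` (positive-rank sum),
#'   `p_value`, `n` (pairs after dropping zero differences), `degenerate`.
#' @examples
#' x <- c(1, 2, 3, 4, 5, 6)
#' wilcoxon_signed_rank(x + 2, x, alternative = "greater")  # exact p = 1/64
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length (paired)")
  if (length(x) == 0) abort("samples must be nonempty")
  d <- x - y
  keep <- d != 0
  n <- sum(keep)
  if (n == 0) {
    return(tibble::tibble(statistic = NA_real_, v = NA_real_, p_value = NA_real_,
                          n = 0L, degenerate = TRUE))
  }
  dk <- d[keep]
  r <- rank(abs(dk))
  v <- sum(r[dk > 0])
  if (n <= 12) {
    # exact conditional null: all 2^n equiprobable sign patterns on the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% r)
    pl <- mean(v_all <= v)
    pg <- mean(v_all >= v)
    p <- switch(alternative,
      two.sided = min(1, 2 * (if (v > n * (n + 1) / 4) pg else pl)),
      greater = pg,
      less = pl
    )
  } else {
    res <- suppressWarnings(
      wilcox.test(x[keep], y[keep], paired = TRUE, alternative = alternative,
                  exact = FALSE, correct = TRUE)
    )
    p <- res$p.value
  }
  tibble::tibble(statistic = min(v, n * (n + 1) / 2 - v), v = v,
                 p_value = p, n = as.integer(n), degenerate = FALSE)
}
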