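#' Exact power of the two-sample t test
#'
#' Power to detect a true group difference `delta` with common within-group
#' SD `sd` and `n` animals per group, via the noncentral t distribution:
#' with df = 2n - 2 and noncentrality (delta/sd) * sqrt(n/2), power is the
#' probability mass of the noncentral t beyond the central-t critical value
#' (both tails summed for a two-sided test).
#'
#' @param delta true group difference (days).
#' @param sd common within-group SD (days).
#' @param n animals per group (>= 2; vectorised).
#' @param alpha significance level (default 0.05).
#' @param sides 1 or 2 (default 2).
#' @return Power in \[0, 1\], same length as `n`.
#' @examples
#' power_two_sample_t(10, 3.93, 4)   # ~0.85: groups of 4 exceed 80% power
#' @export
power_two_sample_t <- function(delta, sd, n, alpha = 0.05, sides = 2) {
  stopifnot(sd > 0, all(n >= 2), alpha > 0, alpha < 1, sides %in% c(1, 2))
  df <- 2 * n - 2
  ncp <- (delta / sd) * sqrt(n / 2)
  if (sides == 2) {
    q <- qt(1 - alpha / 2, df)
    pt(q, df, ncp, lower.tail = FALSE) + pt(-q, df, ncp)
  } else {
    q <- qt(1 - alpha, df)
    pt(q, df, abs(ncp), lower.tail = FALSE)
  }
}

#' Minimum group size for a target power
#'
#' Smallest integer per-group size n >= 2 whose two-sample t-test power
#' ([power_two_sample_t()]) reaches `target_power`; power is monotone in n
#' so a linear search suffices.
#'
#' @param delta,sd,alpha,sides as in [power_two_sample_t()].
#' @param target_power required power, in (alpha, 1).
#' @param n_max search ceiling.
#' @return The smallest qualifying integer n.
#' @examples
#' min_group_size(10, 3.93)  # 4 mice per group
#' min_group_size(10, 4.84)  # 5 mice per group
#' @export
min_group_size <- function(delta, sd, target_power = 0.80, alpha = 0.05,
                           sides = 2, n_max = 10000) {
  stopifnot(target_power > alpha, target_power < 1)
  n <- 2:n_max
  pw <- power_two_sample_t(delta, sd, n, alpha, sides)
  hit <- which(pw >= target_power)
  if (!length(hit))
    stop("target power ", target_power, " not reachable with n <= ", n_max)
  n[hit[1]]
}

#' Monte-Carlo power oracle
#'
#' Estimates two-sample t-test power by simulation: the fraction of
#' replicates in which a two-sided t test at `alpha` rejects, on Normal
#' samples with the given difference and SD.  Serves as an independent check
#' of the analytic noncentral-t computation.
#'
#' @param delta,sd,n,alpha,sides as in [power_two_sample_t()].
#' @param reps number of replicates (>= 100).
#' @param seed optional seed; same seed gives identical estimates.
#' @param var_equal pooled-variance t test (default `TRUE`).
#' @return List: `power`, `se` (binomial standard error), `reps`.
#' @export
monte_carlo_power <- function(delta, sd, n, alpha = 0.05, sides = 2,
                              reps = 1000, seed = NULL, var_equal = TRUE) {
  stopifnot(reps >= 100, n >= 2)
  rej <- with_seed(seed, {
    hits <- logical(reps)
    for (r in seq_len(reps)) {
      x <- rnorm(n, 0, sd); y <- rnorm(n, delta, sd)
      p <- t.test(x, y, var.equal = var_equal,
                  alternative = if (sides == 2) "two.sided" else "less")$p.value
      hits[r] <- p < alpha
    }
    hits
  })
  p <- mean(rej)
  list(power = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Power curve over group sizes
#'
#' @param delta,sd,alpha,sides as in [power_two_sample_t()].
#' @param n vector of per-group sizes.
#' @return Data frame `n`, `power`.
#' @export
power_curve <- function(delta, sd, n = 2:20, alpha = 0.05, sides = 2) {
  data.frame(n = n, power = power_two_sample_t(delta, sd, n, alpha, sides))
}
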