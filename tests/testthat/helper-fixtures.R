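# Shared fixtures and independent oracles for the test suite.

# A vector of length n with exactly the given sample mean and SD.
vec_with_moments <- function(n, mean, sd) {
  z <- as.numeric(scale(seq_len(n)))
  mean + sd * z
}

# Brute-force bout segmentation: walk the series pairwise, splitting on any
# gap strictly greater than max_gap.
oracle_segment <- function(ts, max_gap = 5) {
  if (!length(ts)) return(list())
  groups <- list(ts[1])
  for (i in seq_along(ts)[-1]) {
    if (ts[i] - ts[i - 1] > max_gap)
      groups[[length(groups) + 1]] <- ts[i]
    else
      groups[[length(groups)]] <- c(groups[[length(groups)]], ts[i])
  }
  groups
}

# Brute-force log-rank: tabulate risk sets at each distinct event time and
# accumulate observed-minus-expected and hypergeometric variance for group A.
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1, 2), c(length(time_a), length(time_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Brute-force Kruskal-Wallis H (no ties assumed).
oracle_kw_h <- function(groups) {
  v <- unlist(groups)
  n <- lengths(groups)
  N <- length(v)
  r <- rank(v)
  rs <- split(r, rep(seq_along(groups), n))
  12 / (N * (N + 1)) * sum(vapply(rs, function(x) sum(x)^2, 0) / n) -
    3 * (N + 1)
}

# Small cohorts used across tests (bout resolution keeps them fast).
small_sod1 <- function(n = 4, seed = 11, end_age = NULL) {
  cfg <- wheel_preset("sod1", n_animals = n, seed = seed)
  if (!is.null(end_age)) cfg$end_age <- end_age
  simulate_cohort(cfg, resolution = "bouts")
}
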