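test_that("noncentral-t power matches the null case and an independent routine", {
  # delta 0: power equals the significance level
  expect_equal(power_two_sample_t(0, 4, 8), 0.05, tolerance = 1e-10)
  expect_equal(power_two_sample_t(0, 4, 8, alpha = 0.10, sides = 1), 0.10,
               tolerance = 1e-10)
  # cross-check against stats::power.t.test on a grid: exact agreement
  # one-sided; two-sided differs only by the wrong-direction tail mass,
  # which power.t.test drops and the exact two-sided definition keeps
  for (n in c(3, 5, 10, 20)) {
    for (d_over_s in c(0.5, 1, 2)) {
      d <- d_over_s * 4
      expect_equal(power_two_sample_t(d, 4, n, sides = 1),
                   power.t.test(n = n, delta = d, sd = 4,
                                alternative = "one.sided")$power,
                   tolerance = 1e-9)
      q <- qt(0.975, 2 * n - 2)
      wrong_tail <- pt(-q, 2 * n - 2, (d / 4) * sqrt(n / 2))
      expect_equal(power_two_sample_t(d, 4, n),
                   power.t.test(n = n, delta = d, sd = 4)$power + wrong_tail,
                   tolerance = 1e-9)
    }
  }
  expect_error(power_two_sample_t(10, -1, 4), "sd")
})

test_that("group-size claims from the pooled onset SDs hold", {
  # distance SD 3.93: groups of 4 exceed 80% power for a 10-day difference
  expect_gte(power_two_sample_t(10, 3.93, 4), 0.80)
  expect_equal(min_group_size(10, 3.93), 4)
  # time SD 4.84: groups of 5
  expect_equal(min_group_size(10, 4.84), 5)
  expect_lt(power_two_sample_t(10, 4.84, 4), 0.80)
  # a rotarod-like SD of 9.1 puts groups of 14 at ~80% power
  expect_equal(power_two_sample_t(10, 9.1, 14), 0.80, tolerance = 0.01)
  # a huge effect bottoms out at the search floor
  expect_equal(min_group_size(100, 1), 2)
  expect_error(min_group_size(0.001, 10, n_max = 50), "not reachable")
})

test_that("power is monotone and the size search is exact on a grid", {
  n <- 2:40
  for (ratio in c(0.8, 1.5, 2.5)) {
    pw <- power_two_sample_t(10 * ratio, 10, n)
    expect_true(all(diff(pw) >= 0))
    expect_true(all(diff(pw)[pw[-length(pw)] < 0.999] > 0))
    for (target in c(0.5, 0.8, 0.9)) {
      nn <- min_group_size(10 * ratio, 10, target)
      expect_gte(power_two_sample_t(10 * ratio, 10, nn), target)
      if (nn > 2)
        expect_lt(power_two_sample_t(10 * ratio, 10, nn - 1), target)
    }
  }
  # power increases with delta/sd
  expect_true(all(diff(power_two_sample_t(c(2, 5, 8, 11), 5, 6)) > 0))
})

test_that("Monte-Carlo oracle agrees with the analytic power", {
  # type-I calibration under the null
  mc0 <- monte_carlo_power(0, 3.93, 4, reps = 8000, seed = 1)
  expect_lt(abs(mc0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 8000))
  # the n = 4 group-size claim: within 2 points of the analytic power
  mc <- monte_carlo_power(10, 3.93, 4, reps = 8000, seed = 2)
  expect_lt(abs(mc$power - power_two_sample_t(10, 3.93, 4)), 0.02)
  # determinism under a fixed seed
  expect_identical(monte_carlo_power(5, 4, 6, reps = 200, seed = 9),
                   monte_carlo_power(5, 4, 6, reps = 200, seed = 9))
  # 3x3 grid of (delta/sd, n) within 3 binomial SEs
  set.seed(603)
  for (ratio in c(0.8, 1.5, 2.5)) {
    for (n in c(4, 8, 16)) {
      mcg <- monte_carlo_power(ratio * 6, 6, n, reps = 1500, seed = NULL)
      ana <- power_two_sample_t(ratio * 6, 6, n)
      se <- sqrt(max(ana * (1 - ana), 1e-4) / 1500)
      expect_lt(abs(mcg$power - ana), 3 * se + 1e-6)
    }
  }
})
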