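test_that("capacity curves peak and cease where the disease course says", {
  sod1 <- wheel_preset("sod1")$trajectory
  ages <- 28:135
  cap <- capacity_at_age(sod1, ages)
  peak <- ages[which.max(cap[, "distance"])]
  expect_gte(peak, 38); expect_lte(peak, 42)
  # at and beyond realized cessation all channels are 0
  dr <- list(peak = 40, plateau_start = 60, plateau_end = 100,
             cessation = 125, speed_hold = 118)
  expect_equal(unname(capacity_at_age(sod1, c(125, 130), dr)),
               matrix(0, 2, 3), ignore_attr = TRUE)
  expect_error(capacity_at_age(sod1, -1), "non-negative")

  wt <- wheel_preset("wildtype")$trajectory
  agew <- 20:156
  capw <- capacity_at_age(wt, agew)
  dpeak <- agew[which.max(capw[, "distance"])]
  tpeak <- agew[which.max(capw[, "time"])]
  expect_gte(dpeak, 29); expect_lte(dpeak, 33)
  expect_lte(tpeak, dpeak)  # time peaks first, speeds keep improving
  expect_true(all(diff(capw[, "speed"]) >= 0))
})

test_that("identical seeds reproduce cohorts bit-identically, new seeds differ", {
  a <- small_sod1(n = 3, seed = 5, end_age = 75)
  b <- small_sod1(n = 3, seed = 5, end_age = 75)
  expect_identical(a$daily, b$daily)
  expect_identical(a$weekly, b$weekly)
  d <- small_sod1(n = 3, seed = 6, end_age = 75)
  expect_false(identical(a$daily$distance_km, d$daily$distance_km))

  # per-animal substreams: extending the cohort leaves earlier animals alone
  big <- small_sod1(n = 5, seed = 5, end_age = 75)
  expect_identical(big$daily[big$daily$animal_id %in% a$daily$animal_id, ],
                   a$daily, ignore_attr = TRUE)
})

test_that("event streams stay inside the recording window and the dark phase", {
  cfg <- wheel_preset("sod1", n_animals = 2, seed = 9)
  cfg$end_age <- 45
  coh <- simulate_cohort(cfg, keep_events = TRUE)
  n_checked <- 0
  for (a in coh$animals) {
    for (ev in a$events) {
      if (is.null(ev) || !length(ev$timestamps)) next
      expect_false(is.unsorted(ev$timestamps, strictly = TRUE))
      expect_true(all(ev$timestamps >= 43200 & ev$timestamps < 86400))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("cohort cardinality and config validation", {
  coh <- small_sod1(n = 15, seed = 2, end_age = 50)
  expect_equal(nrow(coh$meta), 15)
  expect_equal(length(unique(coh$daily$animal_id)), 15)

  cfg <- wheel_preset("sod1")
  cfg$n_animals <- 0
  expect_error(simulate_cohort(cfg), "n_animals")
  cfg <- wheel_preset("sod1")
  cfg$censor_rate <- -1
  expect_error(simulate_cohort(cfg), "censor_rate")
})

test_that("simulated days at capacity 1 hit the nominal plateau distance", {
  cfg <- wheel_preset("wildtype")
  nominal <- nominal_daily_distance(cfg)
  set.seed(404)
  dist <- replicate(200, {
    ev <- simulate_day_events(c(time = 1, speed = 1), cfg$bouts,
                              v_top = cfg$speed_mean,
                              speed_shape = cfg$speed_shape)
    length(ev$timestamps) * 0.378 / 1000
  })
  se <- sd(dist) / sqrt(length(dist))
  expect_lt(abs(mean(dist) - nominal), 2 * se)
})

test_that("expected distance scales linearly with the bout-channel capacity", {
  cfg <- wheel_preset("sod1")
  set.seed(405)
  mean_dist <- sapply(c(0.5, 1, 2), function(alpha) {
    mean(replicate(150, {
      ev <- simulate_day_events(c(time = alpha, speed = 1), cfg$bouts,
                                v_top = cfg$speed_mean,
                                speed_shape = cfg$speed_shape)
      length(ev$timestamps) * 0.378 / 1000
    }))
  })
  expect_lt(abs(mean_dist[2] / mean_dist[1] - 2), 0.12)
  expect_lt(abs(mean_dist[3] / mean_dist[2] - 2), 0.12)
  # capacity 0 gives an empty series
  ev0 <- simulate_day_events(c(time = 0, speed = 0), cfg$bouts)
  expect_length(ev0$timestamps, 0)
})

test_that("censored days occur at the configured expected rate", {
  cfg <- wheel_preset("sod1", n_animals = 300, seed = 77)
  cfg$end_age <- 60   # shorter window; the per-animal rate is window-wide
  coh <- simulate_cohort(cfg, resolution = "bouts")
  per_animal <- tapply(coh$daily$censored, coh$daily$animal_id, sum)
  # animals reaching endpoint before end_age observe slightly fewer days
  expected <- cfg$censor_rate *
    mean(tapply(coh$daily$age_day, coh$daily$animal_id, length)) /
    length(seq(cfg$start_age, cfg$end_age))
  se <- sd(per_animal) / sqrt(length(per_animal))
  expect_lt(abs(mean(per_animal) - expected), 2 * se)
})
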