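test_that("rolling baseline finds the best window over non-censored days", {
  expect_equal(rolling_baseline(rep(4.2, 10), window = 3)$baseline_value, 4.2)
  # degenerate window: the series maximum
  b1 <- rolling_baseline(c(1, 9, 3, 5), window = 1)
  expect_equal(b1$baseline_value, 9)
  expect_equal(b1$baseline_day, 2)
  # hand example: the 6,6,6 run wins, centre day reported
  b <- rolling_baseline(c(2, 4, 6, 6, 6, 3, 2), window = 3)
  expect_equal(b$baseline_value, 6)
  expect_equal(b$baseline_day, 4)
  expect_error(rolling_baseline(rep(NA_real_, 10), window = 3),
               "non-censored")

  # brute force over all windows on random censored series
  set.seed(501)
  for (i in 1:50) {
    v <- runif(30, 1, 10)
    cen <- runif(30) < 0.2
    if (sum(!cen) < 5) next
    got <- rolling_baseline(v, censored = cen, window = 5)
    vv <- v[!cen]
    brute <- max(vapply(seq_len(length(vv) - 4),
                        function(j) mean(vv[j:(j + 4)]), 0))
    expect_equal(got$baseline_value, brute)
  }
})

test_that("decline onset triggers on a sustained threshold crossing", {
  # no decline: censored
  r <- detect_decline_onset(1:20, baseline = list(baseline_value = 1,
                                                  baseline_day = 0))
  expect_true(r$censored)

  # baseline 10 fixed at day 40; 7.9 <= 8.0 from day 50, persistence 3
  v <- c(rep(10, 10), rep(7.9, 6))
  r <- detect_decline_onset(v, age = 40:55,
                            baseline = list(baseline_value = 10,
                                            baseline_day = 40))
  expect_false(r$censored)
  expect_equal(r$onset_age, 50)

  # a dip shorter than the persistence requirement does not count
  v2 <- c(rep(10, 5), 7, 7, 10, 10, 10)
  r2 <- detect_decline_onset(v2, age = 40:49, baseline = 10)
  expect_true(r2$censored)

  expect_error(detect_decline_onset(1:5, baseline = 0), "positive")
})

test_that("raising the threshold fraction never gives an earlier onset", {
  set.seed(502)
  for (i in 1:30) {
    v <- 10 * exp(-0.05 * pmax(0, (1:60) - 20)) *
      exp(rnorm(60, 0, 0.08))
    ages <- seq_len(60)
    prev <- -Inf
    for (th in c(0.1, 0.2, 0.3, 0.4)) {
      r <- detect_decline_onset(v, ages, baseline = 10,
                                threshold_fraction = th)
      onset <- if (r$censored) Inf else r$onset_age
      expect_gte(onset, prev)
      prev <- onset
    }
  }
})

test_that("censored days are skipped and never create an onset", {
  set.seed(503)
  for (i in 1:30) {
    v <- 5 + cumsum(abs(rnorm(40, 0.05, 0.1)))  # nondecreasing: no onset
    r0 <- detect_decline_onset(v, baseline = rolling_baseline(v, window = 3))
    expect_true(r0$censored)
    cen <- runif(40) < 0.25
    v2 <- replace(v, cen, NA)
    r1 <- detect_decline_onset(v2, baseline = rolling_baseline(v2, window = 3),
                               censored = cen)
    expect_true(r1$censored)
  }
  # determinism
  v <- 10 * exp(-0.04 * pmax(0, (1:50) - 25))
  a <- detect_decline_onset(v, baseline = 10)
  b <- detect_decline_onset(v, baseline = 10)
  expect_identical(a, b)
})

test_that("onset detection recovers injected changepoints within 2 days", {
  set.seed(504)
  err <- replicate(200, {
    cp <- sample(35:60, 1)
    ages <- 20:90
    level <- ifelse(ages < cp, 10, 7)      # abrupt drop to 70% of baseline
    v <- level * exp(rnorm(length(ages), -0.005, 0.1))  # ~10% daily CV
    bl <- rolling_baseline(v, ages, window = 7)
    r <- detect_decline_onset(v, ages, bl)
    if (r$censored) NA else r$onset_age - cp
  })
  expect_lt(median(abs(err), na.rm = TRUE), 2 + 1e-9)
  expect_lt(mean(is.na(err)), 0.05)
})

test_that("rotarod onset needs a confirmed crossing of 80% of baseline", {
  ages <- seq(35, 35 + 7 * 7, by = 7)
  lat <- c(300, 300, 235, 230, 228, 225, 220, 210)
  r <- rotarod_onset(lat, ages, baseline = 300)
  expect_false(r$censored)
  expect_equal(r$onset_age, ages[3])  # 235 <= 240, confirmed next week

  r2 <- rotarod_onset(rep(250, 8), ages, baseline = 250)
  expect_true(r2$censored)
  # default baseline: best latency of the first test week
  r3 <- rotarod_onset(c(280, 300, 250, 230, 230, 230), seq(35, 70, by = 7))
  expect_equal(r3$baseline_value, 300)
  expect_error(rotarod_onset(numeric()), "empty")
  expect_error(rotarod_onset(c(4, 4), c(35, 42), baseline = 4), "floor")
})

test_that("clinical milestones combine tremor, splay and peak weight", {
  ages <- seq(42, 105, by = 7)
  tremor <- as.integer(ages >= 70)
  splay <- as.integer(ages >= 77)
  w <- c(14.1, 15.0, 15.5, 15.9, 15.9, 15.3, 15.0, 14.2, 13.5, 13.0)
  cm <- clinical_milestones(tremor, splay, w, ages)
  expect_equal(cm$clinical_onset, 77)
  expect_equal(cm$peak_weight_age, ages[4])  # earliest maximum on a tie

  cm2 <- clinical_milestones(tremor, rep(0L, length(ages)), w, ages)
  expect_true(is.na(cm2$clinical_onset))
  expect_error(clinical_milestones(tremor, splay[-1], w[-1], ages),
               "age grid")
})

test_that("onset_fit returns per-animal results with working methods", {
  coh <- small_sod1(n = 4, seed = 21)
  fit <- onset_fit(coh)
  expect_s3_class(fit, "onset_fit")
  o <- fit$onsets
  expect_setequal(unique(o$metric),
                  c("distance", "time", "avg_speed", "rotarod"))
  expect_equal(sum(o$metric == "distance"), 4)
  ok <- !o$censored
  expect_true(all(o$onset_age[ok] > o$baseline_day[ok]))
  expect_true(all(c("distance", "rotarod") %in% names(coef(fit))))
  s <- summary(fit)
  expect_s3_class(s, "summary.onset_fit")
  expect_true(all(s$table$cv_percent >= 0))
  expect_output(print(fit), "Decline-onset fit")
  expect_s3_class(as.data.frame(fit), "data.frame")
})
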