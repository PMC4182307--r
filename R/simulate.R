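# Draw one night of running bouts.
#
# capacity_time scales the expected bout count; capacity_speed scales the
# mean of the per-bout relative-speed distribution.  Per-bout speed is
# v_top * Beta(a, 1) with mean m = speed_shape * capacity_speed: the Beta's
# mass near 1 keeps the nightly maximum speed close to v_top even when the
# mean declines, which is what preserves maximum speed in late disease while
# average speed falls.
draw_bouts <- function(capacity_time, capacity_speed, bouts, v_top,
                       speed_shape, activity_factor = 1,
                       circumference = 0.378) {
  dark_len <- bouts$dark_hours * 3600
  lambda <- bouts$bouts_per_night * capacity_time * activity_factor *
    rlnorm(1, -0.5 * log(1 + bouts$day_cv^2),
           sqrt(log(1 + bouts$day_cv^2)))
  n <- rpois(1, lambda)
  if (n == 0 || capacity_time <= 0 || capacity_speed <= 0)
    return(data.frame(start = numeric(), duration = numeric(),
                      speed = numeric(), n_rev = integer()))
  sdl <- bouts$duration_sdlog
  dur <- pmax(bouts$min_bout_s,
              rlnorm(n, log(bouts$duration_mean_s) - 0.5 * sdl^2, sdl))
  # keep the night physically fillable
  if (sum(dur) > 0.95 * dark_len) dur <- dur * 0.95 * dark_len / sum(dur)

  m <- min(0.98, max(0.02, speed_shape * capacity_speed))
  speed <- pmax(0.5, v_top * rbeta(n, m / (1 - m), 1))
  n_rev <- pmax(2L, as.integer(round(dur * speed / 3.6 / circumference)))

  slack <- dark_len - sum(dur)
  g <- rexp(n + 1)
  g <- g / sum(g) * slack
  start <- bouts$dark_start_hour * 3600 +
    cumsum(g[seq_len(n)]) + c(0, cumsum(dur[-n]))
  data.frame(start = start, duration = dur, speed = speed, n_rev = n_rev)
}

# Expand bouts to revolution timestamps: within a bout the first revolution
# is at the bout start, the remaining n_rev - 1 intervals are multiplicative
# lognormal jitter around the nominal interval, normalised so the bout span
# equals its duration.
events_from_bouts <- function(b, jitter_cv) {
  if (nrow(b) == 0) return(numeric())
  n_int <- b$n_rev - 1L
  total <- sum(n_int)
  id <- rep.int(seq_len(nrow(b)), n_int)
  sdl <- sqrt(log(1 + jitter_cv^2))
  w <- rlnorm(total, 0, sdl)
  wsum <- rowsum(w, id)[, 1]
  ints <- w / wsum[id] * b$duration[id]
  cs <- cumsum(ints)
  offset <- c(0, cs[cumsum(n_int)])[id]
  later <- rep.int(b$start, n_int) + (cs - offset)
  ts <- c(b$start, later)
  sort(ts)
}

#' Simulate one day of rotation events
#'
#' Generates a rotation-event stream for one animal-day: a Poisson number of
#' bouts placed in the dark phase, log-normal bout durations, per-bout
#' speeds, and within-bout revolution intervals of circumference/speed with
#' multiplicative jitter.  Uses the current RNG stream; identical seed and
#' inputs give identical timestamps.
#'
#' @param capacity named vector or list with elements `time` and `speed`
#'   (unitless multipliers, >= 0), e.g. one row of [capacity_at_age()].
#' @param bouts a [bout_params()] object.
#' @param v_top the animal's top within-bout speed, km/h.
#' @param speed_shape mean of the per-bout relative-speed Beta at full speed
#'   capacity.
#' @param activity_factor the animal's overall activity multiplier.
#' @param animal_id,age_day identifiers for the returned series.
#' @param circumference wheel circumference, metres.
#' @return An [event_series()]; empty when capacity is 0.
#' @export
simulate_day_events <- function(capacity, bouts, v_top = 3.15,
                                speed_shape = 0.90, activity_factor = 1,
                                animal_id = "m1", age_day = NA_integer_,
                                circumference = 0.378) {
  stopifnot(inherits(bouts, "bout_params"))
  cap_t <- capacity[["time"]]; cap_s <- capacity[["speed"]]
  if (cap_t < 0 || cap_s < 0) stop("capacity must be non-negative")
  b <- draw_bouts(cap_t, cap_s, bouts, v_top, speed_shape, activity_factor,
                  circumference)
  ts <- events_from_bouts(b, bouts$inter_rotation_cv)
  event_series(animal_id, age_day, ts, circumference)
}

# Daily metrics computed directly from bout-level quantities, skipping the
# revolution stream.  Agrees with the event route up to revolution-level
# jitter and bout merges/splits; used for large simulation studies.
metrics_from_bouts <- function(b, animal_id, age_day, circumference = 0.378) {
  rec <- data.frame(animal_id = animal_id, age_day = age_day,
                    distance_km = 0, time_h = 0,
                    avg_speed_kmh = NA_real_, max_speed_kmh = NA_real_,
                    censored = FALSE, censor_reason = "none",
                    stringsAsFactors = FALSE)
  if (nrow(b) == 0) return(rec)
  rec$distance_km <- sum(b$n_rev) * circumference / 1000
  rec$time_h <- sum(b$duration) / 3600
  if (rec$time_h > 0) {
    rec$avg_speed_kmh <- rec$distance_km / rec$time_h
    rec$max_speed_kmh <- max(3.6 * b$n_rev * circumference / b$duration)
  }
  rec
}

# Weekly rotarod latencies: best of two trials, baseline * capacity with
# multiplicative trial noise, ceiling 300 s, floor 5 s (the recording floor,
# a left-censoring value).
simulate_rotarod <- function(ages, baseline, decline_day, rr) {
  cap <- ifelse(ages < decline_day, 1, exp(-rr$decline_rate * (ages - decline_day)))
  best <- pmax(rlnorm(length(ages), -0.5 * log(1 + rr$trial_cv^2),
                      sqrt(log(1 + rr$trial_cv^2))),
               rlnorm(length(ages), -0.5 * log(1 + rr$trial_cv^2),
                      sqrt(log(1 + rr$trial_cv^2))))
  lat <- baseline * cap * best
  pmin(pmax(lat, rr$floor_s), rr$ceiling_s)
}

simulate_weight <- function(ages, peak_w, peak_age, wt) {
  grow <- 1 - exp(-(ages - 14) / wt$growth_tau)
  ref <- 1 - exp(-(peak_age - 14) / wt$growth_tau)
  w <- ifelse(ages <= peak_age, peak_w * grow / ref,
              peak_w * exp(-wt$late_loss_rate * (ages - peak_age)))
  w * rlnorm(length(ages), -0.5 * log(1 + wt$meas_cv^2),
             sqrt(log(1 + wt$meas_cv^2)))
}

#' Simulate a cohort of animal tracks
#'
#' Generates `config$n_animals` full longitudinal dossiers: daily wheel
#' records (rotation events reduced by the odometer module, with sporadically
#' censored days at the configured rate), weekly rotarod / weight / clinical
#' series, and an endpoint age.  Each animal uses an independent RNG
#' substream derived from the master seed, so the cohort is bit-reproducible
#' and extensible without disturbing existing animals.
#'
#' @param config a [sim_config()], typically from [wheel_preset()].
#' @param resolution `"events"` (default) simulates every wheel revolution
#'   and reduces it through [daily_metrics()]; `"bouts"` computes daily
#'   metrics directly from bout-level quantities (about two orders of
#'   magnitude faster, identical up to revolution-level jitter) for large
#'   simulation studies.
#' @param keep_events if `TRUE` (events resolution only), the raw
#'   [event_series()] objects are retained in each track; memory-heavy for
#'   healthy cohorts (~40k revolutions per animal-day).
#' @return An object of class `"wheel_cohort"`: a list with elements
#'   `config`, `daily` (data frame of daily records across animals),
#'   `weekly` (rotarod/weight/clinical data frame), `meta` (per-animal
#'   metadata: genotype, group, study, endpoint age, realized changepoints
#'   and per-metric realized peak ages), and `animals` (per-animal draws,
#'   plus events when kept).
#' @examples
#' coh <- simulate_cohort(wheel_preset("sod1", n_animals = 2, seed = 1),
#'                        resolution = "bouts")
#' summary(coh)
#' @export
simulate_cohort <- function(config, resolution = c("events", "bouts"),
                            keep_events = FALSE) {
  validate_sim_config(config)
  resolution <- match.arg(resolution)
  traj <- config$trajectory
  ages <- seq(config$start_age, config$end_age)
  week_ages <- seq(config$rotarod$start_age, config$end_age, by = 7)

  daily <- vector("list", config$n_animals)
  weekly <- vector("list", config$n_animals)
  meta <- vector("list", config$n_animals)
  animals <- vector("list", config$n_animals)

  for (i in seq_len(config$n_animals)) {
    res <- with_seed(animal_seed(config$seed, i), {
      id <- sprintf("%s_m%02d", config$study_id, i)
      draws <- draw_changepoints(traj)
      v_top <- max(0.5, rnorm(1, config$speed_mean, config$speed_sd))
      act <- rlnorm(1, -0.5 * log(1 + config$animal_cv^2),
                    sqrt(log(1 + config$animal_cv^2)))

      # disease-side draws
      rr <- config$rotarod
      rr_base <- min(rr$ceiling_s,
                     max(rr$floor_s * 4, rnorm(1, rr$baseline_mean, rr$baseline_sd)))
      rr_decline <- if (is.finite(rr$decline_day_mean))
        rnorm(1, rr$decline_day_mean +
                if (config$wheel_access) rr$wheel_delay else 0,
              rr$decline_day_sd) else Inf
      wt <- config$weight
      wt_peak <- rnorm(1, wt$peak_mean, wt$peak_sd)
      wt_age <- if (config$wheel_access)
        rnorm(1, wt$peak_age_mean, wt$peak_age_sd)
      else rnorm(1, wt$peak_age_mean_nowheel, wt$peak_age_sd_nowheel)
      wt_age <- min(max(wt_age, config$start_age + 7), config$end_age)
      cl <- config$clinical
      tremor_on <- if (is.finite(cl$tremor_mean))
        rnorm(1, cl$tremor_mean, cl$tremor_sd) else Inf
      splay_on <- if (is.finite(cl$splay_mean))
        rnorm(1, cl$splay_mean, cl$splay_sd) else Inf
      endpoint <- if (is.finite(draws$cessation))
        draws$cessation + abs(rnorm(1, config$survival$offset_mean,
                                    config$survival$offset_sd))
      else config$end_age
      endpoint <- min(endpoint, config$end_age)

      obs_ages <- ages[ages <= endpoint]
      day_rec <- NULL
      events <- NULL
      if (config$wheel_access) {
        p_cens <- min(1, config$censor_rate / length(ages))
        cens <- rbinom(length(obs_ages), 1, p_cens) == 1
        cap <- capacity_at_age(traj, obs_ages, draws)
        recs <- vector("list", length(obs_ages))
        if (keep_events) events <- vector("list", length(obs_ages))
        for (k in seq_along(obs_ages)) {
          if (cens[k]) {
            r <- data.frame(animal_id = id, age_day = obs_ages[k],
                            distance_km = 0, time_h = 0,
                            avg_speed_kmh = NA_real_, max_speed_kmh = NA_real_,
                            censored = FALSE, censor_reason = "none",
                            stringsAsFactors = FALSE)
            recs[[k]] <- apply_censoring(
              r, sample(censor_reasons, 1,
                        prob = c(0.5, 0.2, 0.15, 0.1, 0.05)))
            next
          }
          b <- draw_bouts(cap[k, "time"], cap[k, "speed"], config$bouts,
                          v_top, config$speed_shape, act)
          if (resolution == "events") {
            ts <- events_from_bouts(b, config$bouts$inter_rotation_cv)
            ev <- event_series(id, obs_ages[k], ts)
            if (keep_events) events[[k]] <- ev
            recs[[k]] <- daily_metrics(ev)
          } else {
            recs[[k]] <- metrics_from_bouts(b, id, obs_ages[k])
          }
        }
        day_rec <- do.call(rbind, recs)
      }

      wk_ages <- week_ages[week_ages <= endpoint]
      wk <- data.frame(
        animal_id = id, age_day = wk_ages,
        rotarod_s = simulate_rotarod(wk_ages, rr_base, rr_decline, rr),
        weight_g = simulate_weight(wk_ages, wt_peak, wt_age, wt),
        tremor = as.integer(wk_ages >= tremor_on),
        splay = as.integer(wk_ages >= splay_on),
        stringsAsFactors = FALSE)

      peaks <- realized_peaks(traj, draws, config$start_age, config$end_age)
      list(daily = day_rec, weekly = wk,
           meta = data.frame(
             animal_id = id, genotype = config$genotype,
             group = config$group, study_id = config$study_id,
             endpoint_age = endpoint, v_top = v_top,
             peak_age = draws$peak, plateau_start = draws$plateau_start,
             plateau_end = draws$plateau_end, cessation = draws$cessation,
             peak_day_time = peaks[["time"]],
             peak_day_distance = peaks[["distance"]],
             rotarod_baseline = rr_base,
             stringsAsFactors = FALSE),
           animal = list(id = id, draws = draws, v_top = v_top,
                         activity_factor = act, events = events))
    })
    daily[[i]] <- res$daily; weekly[[i]] <- res$weekly
    meta[[i]] <- res$meta; animals[[i]] <- res$animal
  }

  structure(list(config = config,
                 daily = if (config$wheel_access) do.call(rbind, daily) else NULL,
                 weekly = do.call(rbind, weekly),
                 meta = do.call(rbind, meta),
                 animals = animals),
            class = "wheel_cohort")
}

#' @export
print.wheel_cohort <- function(x, ...) {
  cat("<wheel_cohort> ", x$config$genotype, ", n = ", nrow(x$meta),
      ", ages ", x$config$start_age, "-", x$config$end_age, " d",
      if (!x$config$wheel_access) " (no wheel)", "\n", sep = "")
  if (!is.null(x$daily))
    cat("  ", nrow(x$daily), " animal-days (",
        sum(x$daily$censored), " censored)\n", sep = "")
  invisible(x)
}

#' @export
summary.wheel_cohort <- function(object, ...) {
  out <- list(config = object$config, n = nrow(object$meta))
  if (!is.null(object$daily)) {
    d <- object$daily[!object$daily$censored, ]
    out$mean_distance_km <- mean(d$distance_km)
    out$mean_time_h <- mean(d$time_h)
    out$mean_max_speed_kmh <- mean(d$max_speed_kmh, na.rm = TRUE)
    out$censored_days_per_animal <- sum(object$daily$censored) / out$n
  }
  out$mean_endpoint_age <- mean(object$meta$endpoint_age)
  class(out) <- "summary.wheel_cohort"
  out
}

#' @export
print.summary.wheel_cohort <- function(x, ...) {
  cat("Cohort of ", x$n, " ", x$config$genotype, " animals\n", sep = "")
  if (!is.null(x$mean_distance_km))
    cat(sprintf("  mean daily distance %.2f km, time %.2f h, max speed %.2f km/h\n  censored %.2f days/animal\n",
                x$mean_distance_km, x$mean_time_h, x$mean_max_speed_kmh,
                x$censored_days_per_animal))
  cat(sprintf("  mean endpoint age %.1f d\n", x$mean_endpoint_age))
  invisible(x)
}

#' @export
as.data.frame.wheel_cohort <- function(x, ...) x$daily

#' @export
plot.wheel_cohort <- function(x, metric = "distance_km", ...) {
  if (is.null(x$daily)) stop("cohort has no wheel data")
  d <- x$daily[!x$daily$censored, c("animal_id", "age_day", metric)]
  w <- stats::reshape(d, idvar = "age_day", timevar = "animal_id",
                      direction = "wide")
  w <- w[order(w$age_day), ]
  matplot(w$age_day, as.matrix(w[, -1]), type = "l", lty = 1,
          col = grey(0.6), xlab = "Age (days)", ylab = metric, ...)
  avg <- tapply(d[[metric]], d$age_day, mean)
  lines(as.numeric(names(avg)), avg, lwd = 2)
  invisible(x)
}

#' Expected daily distance at capacity 1
#'
#' The analytic expectation of daily distance (km) implied by a
#' configuration's bout model at unit capacity: expected bout count times
#' mean bout duration times mean within-bout speed.  Used as the nominal
#' plateau distance when checking the generator's calibration.
#'
#' @param config a [sim_config()].
#' @return Expected km/day at capacity multipliers of 1.
#' @export
nominal_daily_distance <- function(config) {
  config$bouts$bouts_per_night * config$bouts$duration_mean_s *
    config$speed_mean * config$speed_shape / 3.6 / 1000
}
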