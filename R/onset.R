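#' Baseline for percent-decline onset detection
#'
#' The 20\%-decline rule needs a per-animal reference level.  For daily wheel
#' metrics the default is the *running peak* of a `window`-day rolling mean
#' over non-censored days: the maximum window mean guards against a single
#' spiky day setting an unreachable baseline, while the running peak lets
#' each animal serve as its own control.  `"fixed"` mode simply returns a
#' supplied reference (e.g. a post-training rotarod baseline).
#'
#' @param value per-day metric values.
#' @param age ages (days) matching `value`; defaults to `seq_along(value)`.
#' @param censored logical vector; censored days are skipped, never
#'   interpolated.
#' @param window rolling-mean width in (non-censored) days.
#' @param mode `"running-peak"` or `"fixed"`.
#' @param ref reference value for `"fixed"` mode.
#' @return List with `baseline_value` and `baseline_day` (the age at the
#'   centre of the best window; for `"fixed"` mode the first age).
#' @examples
#' rolling_baseline(c(2, 4, 6, 6, 6, 3, 2), window = 3)  # 6 at day 4
#' @export
rolling_baseline <- function(value, age = seq_along(value), censored = NULL,
                             window = 7,
                             mode = c("running-peak", "fixed"), ref = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(value) == length(age), window >= 1)
  if (is.null(censored)) censored <- is.na(value)
  keep <- !censored & !is.na(value)
  if (mode == "fixed") {
    if (is.null(ref) || ref <= 0) stop("fixed mode needs a positive ref")
    return(list(baseline_value = ref, baseline_day = age[1]))
  }
  v <- value[keep]; a <- age[keep]
  n <- length(v)
  if (n < window)
    stop("need at least ", window, " non-censored days for the baseline")
  cs <- c(0, cumsum(v))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  best <- which.max(means)
  centre <- best + floor((window - 1) / 2)
  list(baseline_value = means[best], baseline_day = a[centre])
}

#' Detect the age at first sustained percent decline
#'
#' The early-readout statistic: the first age, after the baseline day, at
#' which the metric falls to or below `(1 - threshold_fraction)` times the
#' baseline and stays there for `persistence` consecutive evaluable
#' (non-censored) days.  The crossing day itself is reported as the onset.
#' Animals that never satisfy the rule are censored at their last evaluable
#' age.
#'
#' @param value per-day metric values.
#' @param age matching ages, days.
#' @param baseline a list from [rolling_baseline()], or a positive number
#'   (then `baseline_day` defaults to the first age minus one so the whole
#'   series is searched).
#' @param censored logical; censored days are skipped.
#' @param threshold_fraction required fractional decline (default 0.20).
#' @param persistence number of consecutive evaluable days the value must
#'   stay at or below threshold (default 3; use 1 for no confirmation).
#' @param animal_id,metric labels carried into the result.
#' @return A one-row data frame: `animal_id`, `metric`, `baseline_value`,
#'   `baseline_day`, `onset_age`, `censored`, `last_age`.
#' @examples
#' v <- c(rep(10, 10), rep(7.9, 5))
#' detect_decline_onset(v, age = 40:54, baseline = list(baseline_value = 10,
#'                      baseline_day = 40))$onset_age  # 50
#' @export
detect_decline_onset <- function(value, age = seq_along(value),
                                 baseline, censored = NULL,
                                 threshold_fraction = 0.20, persistence = 3,
                                 animal_id = NA_character_,
                                 metric = NA_character_) {
  stopifnot(length(value) == length(age),
            threshold_fraction > 0, threshold_fraction < 1,
            persistence >= 1)
  if (is.numeric(baseline) && length(baseline) == 1)
    baseline <- list(baseline_value = baseline, baseline_day = age[1] - 1)
  if (baseline$baseline_value <= 0) stop("baseline must be positive")
  if (is.null(censored)) censored <- is.na(value)
  keep <- !censored & !is.na(value) & age > baseline$baseline_day
  v <- value[keep]; a <- age[keep]
  out <- data.frame(animal_id = animal_id, metric = metric,
                    baseline_value = baseline$baseline_value,
                    baseline_day = baseline$baseline_day,
                    onset_age = NA_real_, censored = TRUE,
                    last_age = if (length(a)) max(a) else baseline$baseline_day,
                    stringsAsFactors = FALSE)
  n <- length(v)
  if (n < persistence) return(out)
  below <- v <= (1 - threshold_fraction) * baseline$baseline_value
  if (persistence > 1) {
    run <- stats::filter(as.numeric(below), rep(1, persistence),
                         sides = 1)
    hit <- which(run == persistence)
    if (!length(hit)) return(out)
    first <- hit[1] - persistence + 1
  } else {
    hit <- which(below)
    if (!length(hit)) return(out)
    first <- hit[1]
  }
  out$onset_age <- a[first]
  out$censored <- FALSE
  out
}

#' Rotarod 20 percent-decline onset
#'
#' Weekly best-of-two rotarod latencies are compared against the animal's
#' post-training baseline (by default the best latency recorded in the first
#' week of testing).  Onset is the first test age with latency at or below
#' `(1 - threshold_fraction)` of baseline, confirmed at the next test; a
#' final-test crossing with no confirmation opportunity is censored.  The 5 s
#' recording floor is a left-censoring value and still comparable against the
#' threshold.
#'
#' @param latency best-of-two latencies, seconds (capped at 300 s).
#' @param age test ages, days.
#' @param baseline post-training baseline, seconds; default best latency in
#'   the first 7 days of testing.
#' @param threshold_fraction fractional decline (default 0.20).
#' @param animal_id label.
#' @return A one-row data frame as in [detect_decline_onset()].
#' @export
rotarod_onset <- function(latency, age = seq_along(latency) * 7,
                          baseline = NULL, threshold_fraction = 0.20,
                          animal_id = NA_character_) {
  if (!length(latency)) stop("empty latency series")
  stopifnot(length(latency) == length(age))
  if (is.null(baseline))
    baseline <- max(latency[age <= min(age) + 7])
  if (baseline < 5) stop("baseline below the 5 s recording floor")
  below <- latency <= (1 - threshold_fraction) * baseline
  n <- length(below)
  hit <- which(below[-n] & below[-1])
  out <- data.frame(animal_id = animal_id, metric = "rotarod",
                    baseline_value = baseline, baseline_day = age[1],
                    onset_age = NA_real_, censored = TRUE,
                    last_age = max(age), stringsAsFactors = FALSE)
  if (length(hit)) {
    out$onset_age <- age[hit[1]]
    out$censored <- FALSE
  }
  out
}

#' Clinical milestones from weekly scores
#'
#' Clinical disease onset is the first age at which enhanced tremor and
#' defective hind-limb splay are both present; peak-weight age is the age of
#' maximum body weight (earliest if tied).
#'
#' @param tremor,splay 0/1 abnormality indicators on a shared age grid.
#' @param weight weekly body weights, grams (same grid).
#' @param age the age grid, days.
#' @return A list: `clinical_onset` (`NA` if never both abnormal),
#'   `peak_weight_age`, `peak_weight`.
#' @export
clinical_milestones <- function(tremor, splay, weight,
                                age = seq_along(tremor) * 7) {
  if (length(tremor) != length(splay) || length(tremor) != length(age) ||
      length(weight) != length(age))
    stop("score, weight and age series must share one age grid")
  both <- which(tremor > 0 & splay > 0)
  list(clinical_onset = if (length(both)) age[both[1]] else NA_real_,
       peak_weight_age = age[which.max(weight)],
       peak_weight = max(weight))
}

# metric column <-> label mapping for daily tables
.metric_cols <- c(distance = "distance_km", time = "time_h",
                  avg_speed = "avg_speed_kmh")

#' Fit the decline-onset model to a cohort
#'
#' The package's central estimator.  For every animal and every requested
#' wheel metric it estimates a rolling-peak baseline ([rolling_baseline()])
#' and the age of the first sustained 20\% decline
#' ([detect_decline_onset()]); when weekly data are present it adds the
#' rotarod onset, clinical onset and peak-weight age.
#'
#' @param object a [simulate_cohort()] result, or a daily-records data frame
#'   with columns `animal_id`, `age_day`, the metric columns, and `censored`.
#' @param metrics wheel metrics to analyse, a subset of
#'   `c("distance", "time", "avg_speed")`.
#' @param threshold_fraction required fractional decline (default 0.20).
#' @param window baseline rolling-mean width, days (default 7).
#' @param persistence consecutive evaluable days at or below threshold
#'   (default 3).
#' @param weekly optional weekly data frame (`animal_id`, `age_day`,
#'   `rotarod_s`, `weight_g`, `tremor`, `splay`); taken from the cohort when
#'   `object` is a `wheel_cohort`.
#' @param ... unused.
#' @return An object of class `"onset_fit"`: a list with `onsets` (one row
#'   per animal and metric), `milestones` (clinical onset / peak-weight age
#'   per animal, when weekly data exist), and the settings used.
#' @examples
#' coh <- simulate_cohort(wheel_preset("sod1", n_animals = 3),
#'                        resolution = "bouts")
#' fit <- onset_fit(coh)
#' coef(fit)
#' summary(fit)
#' @export
onset_fit <- function(object, metrics = c("distance", "time", "avg_speed"),
                      threshold_fraction = 0.20, window = 7,
                      persistence = 3, weekly = NULL, ...) {
  daily <- NULL
  if (inherits(object, "wheel_cohort")) {
    daily <- object$daily
    weekly <- weekly %||% object$weekly
  } else if (is.data.frame(object)) {
    daily <- object
  } else stop("object must be a wheel_cohort or a daily-records data frame")
  metrics <- match.arg(metrics, several.ok = TRUE)

  rows <- list()
  if (!is.null(daily)) {
    for (id in unique(daily$animal_id)) {
      d <- daily[daily$animal_id == id, ]
      d <- d[order(d$age_day), ]
      for (m in metrics) {
        v <- d[[.metric_cols[[m]]]]
        cen <- d$censored | is.na(v)
        if (sum(!cen) < window) next
        bl <- rolling_baseline(v, d$age_day, cen, window = window)
        rows[[length(rows) + 1]] <- detect_decline_onset(
          v, d$age_day, bl, cen, threshold_fraction, persistence,
          animal_id = id, metric = m)
      }
    }
  }
  milestones <- NULL
  if (!is.null(weekly) && nrow(weekly)) {
    ms <- list()
    for (id in unique(weekly$animal_id)) {
      w <- weekly[weekly$animal_id == id, ]
      w <- w[order(w$age_day), ]
      rows[[length(rows) + 1]] <- rotarod_onset(
        w$rotarod_s, w$age_day, threshold_fraction = threshold_fraction,
        animal_id = id)
      cm <- clinical_milestones(w$tremor, w$splay, w$weight_g, w$age_day)
      ms[[length(ms) + 1]] <- data.frame(
        animal_id = id, clinical_onset = cm$clinical_onset,
        peak_weight_age = cm$peak_weight_age, peak_weight = cm$peak_weight,
        stringsAsFactors = FALSE)
    }
    milestones <- do.call(rbind, ms)
  }
  structure(list(onsets = do.call(rbind, rows), milestones = milestones,
                 settings = list(threshold_fraction = threshold_fraction,
                                 window = window, persistence = persistence),
                 call = match.call()),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat("Decline-onset fit (threshold ",
      100 * x$settings$threshold_fraction, "%, baseline window ",
      x$settings$window, " d, persistence ", x$settings$persistence,
      " d)\n", sep = "")
  tab <- table(x$onsets$metric, ifelse(x$onsets$censored, "censored", "onset"))
  print(tab)
  invisible(x)
}

#' @export
coef.onset_fit <- function(object, ...) {
  o <- object$onsets[!object$onsets$censored, ]
  tapply(o$onset_age, o$metric, mean)[unique(object$onsets$metric)]
}

#' @export
as.data.frame.onset_fit <- function(x, ...) x$onsets

#' @export
summary.onset_fit <- function(object, ...) {
  o <- object$onsets
  per <- lapply(split(o, o$metric), function(d)
    cbind(metric = d$metric[1],
          summarize_study(d$onset_age, d$censored)[-1]))
  out <- do.call(rbind, per[unique(o$metric)])
  rownames(out) <- NULL
  structure(list(table = out, settings = object$settings),
            class = "summary.onset_fit")
}

#' @export
print.summary.onset_fit <- function(x, ...) {
  cat("Age at first sustained ", 100 * x$settings$threshold_fraction,
      "% decline\n", sep = "")
  tab <- x$table
  tab$mean_onset <- round(tab$mean_onset, 1)
  tab$sd_onset <- round(tab$sd_onset, 1)
  tab$cv_percent <- round(tab$cv_percent, 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.onset_fit <- function(x, ...) {
  o <- x$onsets
  mets <- unique(o$metric)
  cols <- seq_along(mets)
  first <- TRUE
  for (i in seq_along(mets)) {
    d <- o[o$metric == mets[i], ]
    cv <- onset_survival_curve(ifelse(d$censored, d$last_age, d$onset_age),
                               !d$censored)
    st <- stats::stepfun(cv$curve$age, c(1, cv$curve$surv))
    if (first) {
      plot(st, do.points = FALSE, xlab = "Age (days)",
           ylab = "Fraction without onset", main = "", ylim = c(0, 1),
           col = cols[i], ...)
      first <- FALSE
    } else lines(st, do.points = FALSE, col = cols[i])
  }
  legend("bottomleft", legend = mets, col = cols, lty = 1, bty = "n")
  invisible(x)
}
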