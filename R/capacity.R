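#' Realize per-animal changepoint ages
#'
#' Draws one animal's realized trajectory changepoints from the population
#' means/SDs in a [trajectory_params()] object (truncated normal, resampled
#' until the ordering peak < plateau start <= plateau end < cessation holds,
#' with a deterministic clip as a last resort).  Uses the current RNG stream.
#'
#' @param traj a `trajectory_params` object.
#' @return A named list of realized ages (days): `peak`, `plateau_start`,
#'   `plateau_end`, `cessation`, `speed_hold`.
#' @export
draw_changepoints <- function(traj) {
  stopifnot(inherits(traj, "trajectory_params"))
  draw1 <- function(m, s) if (is.finite(m)) rnorm(1, m, s) else m
  for (i in 1:50) {
    d <- list(
      peak          = draw1(traj$peak_day, traj$peak_sd),
      plateau_start = draw1(traj$plateau_start_day, traj$plateau_start_sd),
      plateau_end   = draw1(traj$plateau_end_day, traj$plateau_end_sd),
      cessation     = draw1(traj$cessation_day, traj$cessation_sd),
      speed_hold    = draw1(traj$speed_hold_day, traj$speed_hold_sd))
    ok <- d$peak > 0 &&
      (!is.finite(d$cessation) ||
         (d$peak + 3 < d$plateau_start && d$plateau_start <= d$plateau_end &&
          d$plateau_end + 3 < d$cessation &&
          d$speed_hold > d$plateau_start && d$speed_hold < d$cessation))
    if (ok) return(d)
  }
  # deterministic repair: fall back to the population means
  list(peak = traj$peak_day, plateau_start = traj$plateau_start_day,
       plateau_end = traj$plateau_end_day, cessation = traj$cessation_day,
       speed_hold = traj$speed_hold_day)
}

#' Activity capacity at a given age
#'
#' Deterministic piecewise capacity multipliers for one animal, given its
#' realized changepoints.  Three channels are returned: `time` (the bout
#' channel, driving nightly bout count and hence running time), `speed`
#' (within-bout running speed), and `distance` (their product).  The bout
#' channel is piecewise log-linear: juvenile ramp up to 1 at the realized
#' peak, first decline to the plateau fraction by plateau start, flat
#' plateau, then a linear final decline to 0 at cessation (0 afterwards).
#' The speed channel stays near 1 until late disease: it declines only to
#' its own (larger) plateau fraction and holds it until `speed_hold`, so
#' nightly maximum speed is preserved while time and distance fall.  For a
#' wild-type trajectory (no finite cessation) the bout channel drifts down
#' multiplicatively after the peak and the speed channel follows a slow
#' saturating ramp upward.
#'
#' @param traj a [trajectory_params()] object.
#' @param age numeric vector of ages, days; must be non-negative.
#' @param draws realized changepoints for this animal, as returned by
#'   [draw_changepoints()]; defaults to the population means.
#' @return A matrix with one row per age and columns `time`, `speed`,
#'   `distance`.
#' @examples
#' tr <- wheel_preset("sod1")$trajectory
#' cap <- capacity_at_age(tr, 28:135)
#' (28:135)[which.max(cap[, "distance"])]  # ~40 d
#' @export
capacity_at_age <- function(traj, age, draws = NULL) {
  stopifnot(inherits(traj, "trajectory_params"))
  if (any(age < 0)) stop("age must be non-negative")
  if (is.null(draws))
    draws <- list(peak = traj$peak_day,
                  plateau_start = traj$plateau_start_day,
                  plateau_end = traj$plateau_end_day,
                  cessation = traj$cessation_day,
                  speed_hold = traj$speed_hold_day)
  P <- draws$peak; PS <- draws$plateau_start
  PE <- draws$plateau_end; CE <- draws$cessation; SH <- draws$speed_hold
  ramp0 <- P - traj$ramp_days

  # juvenile log-linear ramp shared by both channels (different floors)
  ramp <- function(t, floor_val) {
    f <- exp(log(floor_val) * (P - t) / traj$ramp_days)
    pmax(f, 0.02)
  }

  ct <- numeric(length(age)); cs <- numeric(length(age))
  up <- age <= P
  ct[up] <- ramp(age[up], traj$ramp_floor)

  if (is.finite(CE)) {
    # speed channel: juvenile ramp, then holds 1 until peak + lag before its
    # own (shallower) decline to pf_s, preserved until speed_hold
    SL <- min(P + traj$speed_lag_days, PS - 1)
    pf_s <- traj$plateau_fraction_speed
    cs <- ifelse(age <= P, ramp(age, traj$speed_floor),
          ifelse(age <= SL, 1,
          ifelse(age <= PS, exp(log(pf_s) * (age - SL) / (PS - SL)),
          ifelse(age <= SH, pf_s,
          ifelse(age < CE, pf_s * (CE - age) / (CE - SH), 0)))))
  } else {
    # wild-type: slow saturating improvement, continuous across the peak
    cs <- pmax(1 - traj$speed_ramp_gain * exp(-(age - P) / traj$speed_ramp_tau),
               0.02)
  }

  dn <- !up
  if (any(dn)) {
    t <- age[dn]
    if (is.finite(CE)) {
      pf_t <- traj$plateau_fraction_time
      ct_d <- ifelse(t <= PS, exp(log(pf_t) * (t - P) / (PS - P)),
              ifelse(t <= PE, pf_t,
              ifelse(t < CE, pf_t * (CE - t) / (CE - PE), 0)))
    } else {
      ct_d <- exp(-traj$slow_drift * (t - P))
    }
    ct[dn] <- ct_d
  }
  if (is.finite(CE)) {
    gone <- age >= CE
    ct[gone] <- 0; cs[gone] <- 0
  }
  cbind(time = ct, speed = cs, distance = ct * cs)
}

# Realized peak age per metric: argmax of the noiseless capacity curve on the
# integer age grid (first maximum).
realized_peaks <- function(traj, draws, start_age, end_age) {
  ages <- seq(floor(start_age), ceiling(end_age))
  cap <- capacity_at_age(traj, ages, draws)
  c(time = ages[which.max(cap[, "time"])],
    speed = ages[which.max(cap[, "speed"])],
    distance = ages[which.max(cap[, "distance"])])
}
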