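#' Disease-course trajectory parameters
#'
#' Describes the piecewise activity-capacity course of one genotype.  Capacity
#' is a unitless multiplier in \[0, 1\] applied to the nominal (peak) activity
#' level, with two channels: a *bout* channel driving how much the animal runs
#' (nightly bout count, hence time and distance) and a *speed* channel driving
#' how fast it runs within bouts.  Changepoint ages are population means with
#' SDs; each simulated animal realizes its own draws (see
#' [draw_changepoints()]).
#'
#' For the SOD1-like course the shape is: juvenile ramp up to a peak near 40 d
#' of age, first decline to a plateau reached near 60 d, stable plateau, second
#' decline from about 100 d, cessation of running by about 130 d.  Top running
#' speed is preserved until late disease (`speed_hold_day`).  For the wild-type
#' course: ramp to a peak near 29-31 d, then a slow multiplicative drift
#' downward in the bout channel while the speed channel keeps improving
#' slightly, so running time peaks a couple of days before distance and speeds
#' never show an early peak.
#'
#' @param peak_day,peak_sd mean and SD (days of age) of peak bout-channel
#'   activity; for the disease course this is also where the first decline
#'   begins.
#' @param ramp_days length (days) of the juvenile log-linear ramp ending at
#'   `peak_day`.
#' @param ramp_floor bout-channel capacity at the start of the ramp.
#' @param plateau_fraction_time,plateau_fraction_speed capacity retained on the
#'   disease plateau, per channel (0-1\]; the distance channel is their
#'   product.
#' @param plateau_start_day,plateau_start_sd mean/SD age (days) the first
#'   decline ends and the plateau begins.
#' @param plateau_end_day,plateau_end_sd mean/SD age (days) the second decline
#'   begins (bout channel).
#' @param cessation_day,cessation_sd mean/SD age (days) at which running
#'   ceases; capacity is 0 for all channels at and after the realized value.
#' @param speed_hold_day,speed_hold_sd mean/SD age (days) until which the
#'   speed channel holds its plateau before its final decline; late enough
#'   that maximum speed is preserved through ~120 d.
#' @param speed_lag_days days after the bout-channel peak before the speed
#'   channel starts its first decline: running slows a little later than it
#'   shortens, which is what lets distance (their product) cross the 20\%
#'   threshold a few days before time and average speed do.
#' @param slow_drift per-day multiplicative decline of the bout channel after
#'   the peak (wild-type only; 0 for the disease course).
#' @param speed_ramp_gain,speed_ramp_tau wild-type speed-channel saturating
#'   ramp `1 - gain * exp(-(age - peak)/tau)`: speeds keep improving slowly
#'   for the whole window, which places the distance peak about two days
#'   after the time peak.
#' @param speed_floor speed-channel capacity at the start of the juvenile
#'   ramp.
#' @return An object of class `"trajectory_params"` (a list).
#' @seealso [wheel_preset()] for calibrated defaults, [capacity_at_age()].
#' @export
trajectory_params <- function(peak_day, peak_sd = 0,
                              ramp_days = 12, ramp_floor = 0.35,
                              plateau_fraction_time = 1,
                              plateau_fraction_speed = 1,
                              plateau_start_day = Inf, plateau_start_sd = 0,
                              plateau_end_day = Inf, plateau_end_sd = 0,
                              cessation_day = Inf, cessation_sd = 0,
                              speed_hold_day = Inf, speed_hold_sd = 0,
                              speed_lag_days = 0,
                              slow_drift = 0,
                              speed_ramp_gain = 0, speed_ramp_tau = 20,
                              speed_floor = 0.85) {
  stopifnot(peak_day > 0, peak_sd >= 0, ramp_days > 0,
            ramp_floor > 0, ramp_floor <= 1,
            plateau_fraction_time > 0, plateau_fraction_time <= 1,
            plateau_fraction_speed > 0, plateau_fraction_speed <= 1,
            slow_drift >= 0, speed_ramp_gain >= 0, speed_ramp_tau > 0,
            speed_lag_days >= 0)
  if (is.finite(cessation_day) &&
      !(peak_day < plateau_start_day && plateau_start_day <= plateau_end_day &&
        plateau_end_day < cessation_day))
    stop("changepoint means must be ordered: peak < plateau start <= plateau end < cessation")
  structure(as.list(environment()), class = "trajectory_params")
}

#' Within-night bout-structure parameters
#'
#' The event-level generative model behind the odometer readings: activity is
#' a Poisson number of running bouts per dark phase, bout durations are
#' log-normal, and within a bout revolution intervals equal
#' circumference/speed with multiplicative jitter.  The recording window is a
#' fixed 24 h calendar day aligned to the light cycle (odometer read each
#' morning); the 12 h dark phase occupies the second half of the window.
#'
#' @param bouts_per_night mean bout count per dark phase at capacity 1.
#' @param duration_mean_s mean bout duration, seconds.
#' @param duration_sdlog SD of log bout duration.
#' @param min_bout_s minimum bout duration, seconds.
#' @param day_cv coefficient of variation of the night-to-night lognormal
#'   activity multiplier.
#' @param inter_rotation_cv coefficient of variation of the multiplicative
#'   jitter on within-bout revolution intervals.
#' @param dark_start_hour hour of the recording window at which the dark
#'   phase begins (the window starts at lights-on).
#' @param dark_hours length of the dark phase, hours.
#' @return An object of class `"bout_params"` (a list).
#' @export
bout_params <- function(bouts_per_night = 105, duration_mean_s = 110,
                        duration_sdlog = 0.6, min_bout_s = 5,
                        day_cv = 0.12, inter_rotation_cv = 0.05,
                        dark_start_hour = 12, dark_hours = 12) {
  stopifnot(bouts_per_night > 0, duration_mean_s > 0, duration_sdlog >= 0,
            min_bout_s > 0, day_cv >= 0, inter_rotation_cv >= 0,
            dark_start_hour >= 0, dark_start_hour + dark_hours <= 24,
            dark_hours == 12)
  structure(as.list(environment()), class = "bout_params")
}

#' Simulation configuration for one cohort
#'
#' Bundles everything needed to simulate a cohort of animals: genotype,
#' cohort size, observation window, activity trajectory and bout structure,
#' running-speed distribution, censoring rate, and the weekly rotarod,
#' weight, clinical-score and survival models.  Use [wheel_preset()] for the
#' calibrated `"wildtype"` and `"sod1"` presets rather than filling fields by
#' hand.
#'
#' @param genotype `"wild-type"` or `"SOD1-like"`.
#' @param n_animals number of animals (>= 1).
#' @param start_age,end_age observation window, days of age.
#' @param seed master seed; one independent substream is derived per animal.
#' @param trajectory a [trajectory_params()] object.
#' @param bouts a [bout_params()] object.
#' @param speed_mean,speed_sd between-animal distribution (km/h) of the
#'   animal's top within-bout running speed.
#' @param speed_shape mean of the per-bout relative-speed distribution
#'   (Beta(a, 1) with mean `speed_shape` at full speed capacity); the Beta's
#'   mass near 1 is what preserves the nightly maximum speed while the mean
#'   declines.
#' @param animal_cv between-animal coefficient of variation of overall
#'   activity level.
#' @param censor_rate expected censored recording days per animal over the
#'   whole window (hardware faults: jammed wheel, unreset odometer, detached
#'   reed switch, water leak).
#' @param wheel_access logical; `FALSE` simulates a no-wheel control arm
#'   (no wheel data; rotarod decline earlier, peak weight earlier).
#' @param rotarod list: `baseline_mean`, `baseline_sd` (s), `trial_cv`,
#'   `decline_day_mean`, `decline_day_sd`, `decline_rate` (per day),
#'   `wheel_delay` (days added to the decline day when running wheels are
#'   available), `ceiling_s`, `floor_s`, `start_age`.
#' @param weight list: `peak_mean`, `peak_sd` (g), `peak_age_mean`,
#'   `peak_age_sd`, `peak_age_mean_nowheel`, `peak_age_sd_nowheel` (days),
#'   `growth_tau` (days), `late_loss_rate` (per day), `meas_cv`.
#' @param clinical list: `tremor_mean`, `tremor_sd`, `splay_mean`,
#'   `splay_sd` (days; `Inf` means never abnormal).
#' @param survival list: `offset_mean`, `offset_sd` -- the humane endpoint is
#'   the realized cessation age plus a truncated-normal offset (days).
#' @param study_id,group labels carried into outputs.
#' @return An object of class `"sim_config"` (a list).
#' @export
sim_config <- function(genotype = c("SOD1-like", "wild-type"),
                       n_animals = 15, start_age = 28, end_age = 135,
                       seed = 1,
                       trajectory = trajectory_params(peak_day = 40),
                       bouts = bout_params(),
                       speed_mean = 3.15, speed_sd = 0.10,
                       speed_shape = 0.90,
                       animal_cv = 0.10, censor_rate = 0.23,
                       wheel_access = TRUE,
                       rotarod = list(), weight = list(), clinical = list(),
                       survival = list(),
                       study_id = "study1", group = NULL) {
  genotype <- match.arg(genotype)
  cfg <- list(
    genotype = genotype, n_animals = n_animals,
    start_age = start_age, end_age = end_age, seed = seed,
    trajectory = trajectory, bouts = bouts,
    speed_mean = speed_mean, speed_sd = speed_sd, speed_shape = speed_shape,
    animal_cv = animal_cv, censor_rate = censor_rate,
    wheel_access = wheel_access,
    rotarod = utils::modifyList(list(
      baseline_mean = 235, baseline_sd = 30, trial_cv = 0.08,
      decline_day_mean = 44.5, decline_day_sd = 9, decline_rate = 0.030,
      wheel_delay = 10.7, ceiling_s = 300, floor_s = 5, start_age = 35),
      rotarod),
    weight = utils::modifyList(list(
      peak_mean = 15.9, peak_sd = 0.7,
      peak_age_mean = 91.0, peak_age_sd = 16.1,
      peak_age_mean_nowheel = 64.4, peak_age_sd_nowheel = 22.0,
      growth_tau = 25, late_loss_rate = 0.004, meas_cv = 0.01),
      weight),
    clinical = utils::modifyList(list(
      tremor_mean = 82, tremor_sd = 9, splay_mean = 86, splay_sd = 9),
      clinical),
    survival = utils::modifyList(list(offset_mean = 4, offset_sd = 2),
                                 survival),
    study_id = study_id,
    group = group %||% if (wheel_access) "running" else "non-running")
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  if (!inherits(config, "sim_config")) stop("not a sim_config object")
  chk <- function(ok, field)
    if (!isTRUE(ok)) stop("invalid sim_config field: ", field, call. = FALSE)
  chk(is.numeric(config$n_animals) && config$n_animals >= 1, "n_animals")
  chk(config$start_age >= 0, "start_age")
  chk(config$start_age < config$end_age, "start_age/end_age")
  chk(config$censor_rate >= 0, "censor_rate")
  chk(config$speed_mean > 0 && config$speed_mean < 10, "speed_mean")
  chk(config$speed_sd >= 0, "speed_sd")
  chk(config$speed_shape > 0 && config$speed_shape < 1, "speed_shape")
  chk(config$animal_cv >= 0, "animal_cv")
  chk(inherits(config$trajectory, "trajectory_params"), "trajectory")
  chk(inherits(config$bouts, "bout_params"), "bouts")
  chk(config$rotarod$baseline_sd >= 0, "rotarod$baseline_sd")
  chk(config$weight$peak_sd >= 0, "weight$peak_sd")
  invisible(config)
}

#' Calibrated cohort presets
#'
#' Returns a ready-to-use [sim_config()] for one of the study conditions:
#'
#' * `"wildtype"`: healthy C57BL/6-like females observed for 130 days from
#'   26 d of age.  Activity ramps to a peak (running time near day 29,
#'   distance near day 31), then drifts slowly downward while average and
#'   maximum speed stay stable or improve.  Calibrated so the post-peak
#'   plateau means are 15.07 km/day and 5.06 h/day.
#' * `"sod1"`: SOD1-G93A-like females with running wheels, observed from
#'   28 d.  Activity peaks near 40 d, declines to a plateau reached near
#'   60 d, declines again from about 100 d and ceases by about 130 d;
#'   maximum speed stays within 2.8-3.5 km/h until about 120 d.  Calibrated
#'   so the mean age of the first sustained 20\% decline is about 44.3 d for
#'   distance, 45.5 d for time and 47.1 d for average speed.
#' * `"sod1_norunning"`: the no-wheel control arm (locked wheel); only the
#'   weekly rotarod/weight/clinical/survival series are produced, with the
#'   rotarod 20\%-decline age near 55 d.
#'
#' @param name preset name.
#' @param n_animals,seed,... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
wheel_preset <- function(name = c("sod1", "wildtype", "sod1_norunning"),
                         n_animals = 15, seed = 1, ...) {
  name <- match.arg(name)
  switch(name,
    wildtype = sim_config(
      genotype = "wild-type", n_animals = n_animals,
      start_age = 26, end_age = 156, seed = seed,
      trajectory = trajectory_params(
        peak_day = 29, peak_sd = 2, ramp_days = 10, ramp_floor = 0.30,
        slow_drift = 0.0012, speed_ramp_gain = 0.0266, speed_ramp_tau = 20,
        speed_floor = 0.85),
      bouts = bout_params(bouts_per_night = 176.1),
      speed_mean = 3.253, speed_sd = 0.12, speed_shape = 0.92,
      animal_cv = 0.12,
      clinical = list(tremor_mean = Inf, tremor_sd = 0,
                      splay_mean = Inf, splay_sd = 0),
      weight = list(peak_mean = 22, peak_sd = 1.2, peak_age_mean = 150,
                    peak_age_sd = 10, late_loss_rate = 0),
      rotarod = list(decline_day_mean = Inf, decline_day_sd = 0),
      study_id = "wt1", group = "wild-type",
      ...),
    sod1 = sim_config(
      genotype = "SOD1-like", n_animals = n_animals,
      start_age = 28, end_age = 135, seed = seed,
      trajectory = trajectory_params(
        peak_day = 39.6, peak_sd = 3.6, ramp_days = 12, ramp_floor = 0.35,
        plateau_fraction_time = 0.20, plateau_fraction_speed = 0.307,
        speed_lag_days = 3.0,
        plateau_start_day = 60, plateau_start_sd = 4,
        plateau_end_day = 100, plateau_end_sd = 6,
        cessation_day = 128, cessation_sd = 6,
        speed_hold_day = 120, speed_hold_sd = 4,
        speed_floor = 0.85),
      bouts = bout_params(bouts_per_night = 105),
      speed_mean = 3.15, speed_sd = 0.10, speed_shape = 0.90,
      animal_cv = 0.10,
      study_id = "study1", group = "running",
      ...),
    sod1_norunning = {
      cfg <- wheel_preset("sod1", n_animals = n_animals, seed = seed, ...)
      cfg$wheel_access <- FALSE
      cfg$group <- "non-running"
      cfg
    })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$genotype, ", n = ", x$n_animals,
      ", ages ", x$start_age, "-", x$end_age, " d, seed ", x$seed,
      if (!x$wheel_access) ", no wheel" else "", "\n", sep = "")
  invisible(x)
}
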