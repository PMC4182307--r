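#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing the standard
#' CSVs plus a JSON run manifest into `out_dir`.  Stages:
#'
#' * `simulate` -- simulate a cohort from `config` and write `daily.csv`,
#'   `weekly.csv`, `meta.csv` (the odometer reduction is applied in memory;
#'   set `keep_events = TRUE` to also write `events.csv`, practical only for
#'   small cohorts).
#' * `metrics` -- reduce an existing `events.csv` to `daily.csv`.
#' * `onset` -- fit the decline-onset model to `daily.csv` (+ `weekly.csv`
#'   when present) and write `onsets.csv`.
#' * `cohort` -- summarise `onsets.csv` into `summaries.csv`.
#' * `power` -- write `power.csv` (power curve over group sizes) from
#'   `delta`/`sd`, or from the fitted distance-onset SD when available.
#'
#' All randomness derives from `seed` (default: the config's master seed);
#' rerunning with identical inputs reproduces byte-identical outputs, which
#' the manifest records via MD5 digests.
#'
#' @param config a [sim_config()] or preset name for [wheel_preset()].
#' @param stages subset of
#'   `c("simulate", "metrics", "onset", "cohort", "power")`.
#' @param out_dir output directory (created if needed).
#' @param seed master seed override.
#' @param resolution,keep_events passed to [simulate_cohort()].
#' @param delta,sd,target_power power-stage inputs (defaults: 10-day
#'   difference; SD from the fitted distance onsets).
#' @param ... passed to [onset_fit()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = "sod1",
                         stages = c("simulate", "onset", "cohort", "power"),
                         out_dir = ".", seed = NULL,
                         resolution = "events", keep_events = FALSE,
                         delta = 10, sd = NULL, target_power = 0.80, ...) {
  all_stages <- c("simulate", "metrics", "onset", "cohort", "power")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  if (is.character(config)) config <- wheel_preset(config)
  validate_sim_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  written <- character()
  log_info <- function(...) message("[runwheel] ", sprintf(...))

  need <- function(file, producer) {
    if (!file.exists(path(file)))
      stop("missing upstream output '", file, "': run the '", producer,
           "' stage first", call. = FALSE)
  }

  if ("simulate" %in% stages) {
    coh <- simulate_cohort(config, resolution = resolution,
                           keep_events = keep_events)
    if (!is.null(coh$daily)) {
      write_table(coh$daily, path("daily.csv"), "daily")
      written <- c(written, "daily.csv")
      log_info("simulate: %d animals, %d animal-days (%d censored)",
               nrow(coh$meta), nrow(coh$daily), sum(coh$daily$censored))
    }
    write_table(coh$weekly, path("weekly.csv"), "weekly")
    write_table(coh$meta, path("meta.csv"), "meta")
    written <- c(written, "weekly.csv", "meta.csv")
    if (keep_events) {
      write_table(events_table(coh), path("events.csv"), "events")
      written <- c(written, "events.csv")
    }
  }
  if ("metrics" %in% stages) {
    need("events.csv", "simulate")
    ev <- load_table(path("events.csv"), "events")
    write_table(daily_from_events(ev), path("daily.csv"), "daily")
    written <- c(written, "daily.csv")
    log_info("metrics: reduced %d events", nrow(ev))
  }
  fit <- NULL
  if ("onset" %in% stages) {
    need("daily.csv", "metrics")
    daily <- load_table(path("daily.csv"), "daily")
    weekly <- if (file.exists(path("weekly.csv")))
      load_table(path("weekly.csv"), "weekly") else NULL
    fit <- onset_fit(daily, weekly = weekly, ...)
    write_table(fit$onsets, path("onsets.csv"), "onsets")
    written <- c(written, "onsets.csv")
    log_info("onset: %d animal-metric results (%d censored)",
             nrow(fit$onsets), sum(fit$onsets$censored))
  }
  if ("cohort" %in% stages) {
    need("onsets.csv", "onset")
    on <- load_table(path("onsets.csv"), "onsets")
    per <- lapply(split(on, on$metric), function(d) {
      # metrics with fewer than 2 observed onsets cannot be summarised
      if (sum(!d$censored) < 2) {
        log_info("cohort: skipping metric '%s' (<2 observed onsets)",
                 d$metric[1])
        return(NULL)
      }
      s <- summarize_study(d$onset_age, d$censored,
                           study_id = config$study_id)
      cbind(s[, 1:2], metric = d$metric[1], s[, 3:5])
    })
    per <- per[!vapply(per, is.null, TRUE)]
    if (!length(per))
      stop("no metric has >= 2 observed onsets; nothing to summarise")
    summ <- do.call(rbind, per)
    write_table(summ, path("summaries.csv"), "summaries")
    written <- c(written, "summaries.csv")
  }
  if ("power" %in% stages) {
    if (is.null(sd)) {
      if (file.exists(path("summaries.csv"))) {
        summ <- load_table(path("summaries.csv"), "summaries")
        sd <- summ$sd_onset[summ$metric == "distance"][1]
      }
      if (is.null(sd) || is.na(sd))
        stop("power stage needs 'sd' (or an upstream summaries.csv)")
    }
    pc <- power_curve(delta, sd)
    pc$min_n <- min_group_size(delta, sd, target_power)
    utils::write.csv(pc, path("power.csv"), row.names = FALSE)
    written <- c(written, "power.csv")
    log_info("power: delta %.1f d, sd %.2f d -> n = %d per group",
             delta, sd, pc$min_n[1])
  }

  manifest <- list(
    package = "runwheel",
    config = unclass(config[c("genotype", "n_animals", "start_age",
                              "end_age", "seed", "study_id", "group",
                              "censor_rate")]),
    seed = config$seed, stages = stages,
    outputs = as.list(tools::md5sum(vapply(unique(written), path, ""))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
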