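# CSV schemas shared by the pipeline stages.  All files are comma-separated
# UTF-8 with a header row, "." decimal separator, and empty field = missing.
.schemas <- list(
  events = list(
    cols = c(animal_id = "character", age_day = "integer",
             timestamp_s = "numeric")),
  daily = list(
    cols = c(animal_id = "character", age_day = "integer",
             distance_km = "numeric", time_h = "numeric",
             avg_speed_kmh = "numeric", max_speed_kmh = "numeric",
             censored = "logical", censor_reason = "character")),
  weekly = list(
    cols = c(animal_id = "character", age_day = "integer",
             rotarod_s = "numeric", weight_g = "numeric",
             tremor = "integer", splay = "integer")),
  onsets = list(
    cols = c(animal_id = "character", metric = "character",
             baseline_value = "numeric", baseline_day = "numeric",
             onset_age = "numeric", censored = "logical")),
  meta = list(
    cols = c(animal_id = "character", genotype = "character",
             group = "character", study_id = "character",
             endpoint_age = "numeric")),
  summaries = list(
    cols = c(study_id = "character", n = "integer", metric = "character",
             mean_onset = "numeric", sd_onset = "numeric",
             cv_percent = "numeric")))

#' Read and validate a pipeline table
#'
#' Reads one of the pipeline's CSV schemas and validates it: required
#' columns present, numerics parseable, metric values non-negative on
#' non-censored rows, and event timestamps within \[0, 86400) and strictly
#' increasing within each animal-day.  Violations are reported with row
#' numbers.
#'
#' @param path CSV file path.
#' @param schema one of `"events"`, `"daily"`, `"weekly"`, `"onsets"`,
#'   `"meta"`, `"summaries"`.
#' @return A validated data frame (possibly empty, with a warning).
#' @export
load_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- .schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = "")
  missing_cols <- setdiff(names(sch$cols), names(df))
  if (length(missing_cols))
    stop("schema '", schema, "': missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) {
    warning("empty table (valid header): ", path)
    return(df)
  }
  for (cn in names(sch$cols)) {
    target <- sch$cols[[cn]]
    v <- df[[cn]]
    conv <- switch(target,
                   numeric = suppressWarnings(as.numeric(v)),
                   integer = suppressWarnings(as.integer(v)),
                   logical = as.logical(v),
                   character = as.character(v))
    bad <- which(!is.na(v) & is.na(conv))
    if (length(bad))
      stop("schema '", schema, "', column '", cn, "': unparseable value",
           " at row ", bad[1])
    df[[cn]] <- conv
  }
  if (schema %in% c("daily")) {
    num <- c("distance_km", "time_h", "avg_speed_kmh", "max_speed_kmh")
    for (cn in num) {
      bad <- which(!df$censored & !is.na(df[[cn]]) & df[[cn]] < 0)
      if (length(bad))
        stop("schema 'daily', column '", cn, "': negative value at row ",
             bad[1])
    }
  }
  if (schema == "events") {
    bad <- which(df$timestamp_s < 0 | df$timestamp_s >= 86400)
    if (length(bad))
      stop("schema 'events': timestamp out of [0, 86400) at row ", bad[1])
    key <- paste(df$animal_id, df$age_day)
    for (k in unique(key)) {
      ts <- df$timestamp_s[key == k]
      if (is.unsorted(ts, strictly = TRUE))
        stop("schema 'events': timestamps not strictly increasing for ",
             "animal-day ", k, " (row ",
             which(key == k)[which(diff(ts) <= 0)[1] + 1], ")")
    }
  }
  df
}

#' Write a pipeline table
#'
#' @param df data frame matching one of the pipeline schemas.
#' @param path output CSV path.
#' @param schema schema name (columns are subset/ordered accordingly).
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  cols <- names(.schemas[[schema]]$cols)
  keep <- intersect(cols, names(df))
  utils::write.csv(df[keep], path, row.names = FALSE, na = "")
  invisible(path)
}

# Events of a cohort as a long data frame (keep_events cohorts only).
events_table <- function(cohort) {
  stopifnot(inherits(cohort, "wheel_cohort"))
  rows <- list()
  for (a in cohort$animals) {
    if (is.null(a$events)) next
    for (ev in a$events) {
      if (is.null(ev) || !length(ev$timestamps)) next
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = ev$animal_id, age_day = ev$age_day,
        timestamp_s = ev$timestamps, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(animal_id = character(), age_day = integer(),
                      timestamp_s = numeric()))
  do.call(rbind, rows)
}

# Reduce an events table to daily records through the odometer module.
daily_from_events <- function(events_df, circumference = 0.378,
                              max_gap = 5) {
  key <- unique(events_df[c("animal_id", "age_day")])
  recs <- vector("list", nrow(key))
  for (i in seq_len(nrow(key))) {
    sel <- events_df$animal_id == key$animal_id[i] &
      events_df$age_day == key$age_day[i]
    ev <- event_series(key$animal_id[i], key$age_day[i],
                       events_df$timestamp_s[sel], circumference)
    recs[[i]] <- daily_metrics(ev, max_gap = max_gap)
  }
  do.call(rbind, recs)
}
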