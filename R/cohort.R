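#' Summarise one study's onset ages
#'
#' Mean, sample SD (n - 1 denominator) and coefficient of variation
#' (100 * SD / mean) of the non-censored onset ages for one study and
#' metric.  Censored animals are excluded, matching how multi-study summary
#' tables report only mice with an observed onset.  Values are kept at full
#' precision; round for display only.
#'
#' @param onset_age numeric onset ages (days); `NA` allowed for censored.
#' @param censored optional logical; censored entries are dropped.
#' @param study_id optional label.
#' @return One-row data frame: `study_id`, `n`, `mean_onset`, `sd_onset`,
#'   `cv_percent`.
#' @export
summarize_study <- function(onset_age, censored = NULL, study_id = NA) {
  if (!is.null(censored)) onset_age <- onset_age[!censored]
  onset_age <- onset_age[!is.na(onset_age)]
  if (length(onset_age) < 2)
    stop("need at least 2 non-censored onsets to summarise a study")
  m <- mean(onset_age); s <- sd(onset_age)
  data.frame(study_id = study_id, n = length(onset_age), mean_onset = m,
             sd_onset = s, cv_percent = 100 * s / m)
}

#' Between-study coefficient of variation
#'
#' Reproducibility across studies: 100 times the sample SD of the per-study
#' mean onset ages divided by their mean.
#'
#' @param study_means one mean onset age per study (>= 2 studies).
#' @return The between-study CV, percent.
#' @examples
#' between_study_cv(c(45.57, 43.13, 44.56, 44.29, 45.00, 46.07, 43.93))
#' @export
between_study_cv <- function(study_means) {
  study_means <- study_means[!is.na(study_means)]
  if (length(study_means) < 2) stop("need at least 2 studies")
  100 * sd(study_means) / mean(study_means)
}

#' Onset survival curve
#'
#' Product-limit (Kaplan-Meier) estimate treating onset as the event, so
#' that onset distributions can be compared between groups and between
#' experiments like survival data.  Animals without an observed onset
#' contribute risk-time up to their last evaluable age.
#'
#' @param time event or censoring ages, days.
#' @param event logical/0-1: `TRUE` if onset observed.
#' @return An object of class `"onset_curve"`: list with `curve` (data frame
#'   `age`, `surv`, `n_risk`, `n_event`), the underlying
#'   [survival::survfit] object, and the inputs.
#' @export
onset_survival_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(curve = data.frame(age = fit$time, surv = fit$surv,
                                    n_risk = fit$n.risk,
                                    n_event = fit$n.event),
                 fit = fit, time = time, event = event),
            class = "onset_curve")
}

#' @export
print.onset_curve <- function(x, ...) {
  cat("Onset survival curve: ", sum(x$event), " events, ",
      sum(1 - x$event), " censored\n", sep = "")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @export
plot.onset_curve <- function(x, ...) {
  plot(x$fit, xlab = "Age (days)", ylab = "Fraction without onset", ...)
  invisible(x)
}

#' Log-rank comparison of two onset curves
#'
#' Standard one-degree-of-freedom log-rank (Mantel-Cox) test of the onset
#' distributions of two groups.
#'
#' @param time_a,event_a ages and event indicators for group A.
#' @param time_b,event_b likewise for group B.
#' @return List: `chisq`, `df`, `p_value`, plus observed and expected event
#'   counts per group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  if (sum(event_a) + sum(event_b) < 1) stop("need at least one event")
  time <- c(time_a, time_b)
  event <- as.integer(c(event_a, event_b))
  grp <- factor(rep(c("A", "B"), c(length(time_a), length(time_b))))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- sd_$chisq
  list(chisq = chisq, df = 1,
       p_value = stats::pchisq(chisq, 1, lower.tail = FALSE),
       observed = as.numeric(sd_$obs), expected = as.numeric(sd_$exp))
}

#' Two-group comparison of onset ages
#'
#' Two-sided comparison of non-censored onset ages between two groups:
#' classic pooled-variance unpaired t test (the era's default; Welch
#' available via `var_equal = FALSE`) or the Mann-Whitney rank test.
#'
#' @param a,b onset ages per group (NAs dropped); each group needs n >= 2.
#' @param test `"t"` or `"mann-whitney"`.
#' @param var_equal pooled variance for the t test (default `TRUE`).
#' @return List: `statistic`, `p_value`, `test`, and the group means.
#' @export
compare_groups <- function(a, b, test = c("t", "mann-whitney"),
                           var_equal = TRUE) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 non-censored onsets")
  if (test == "t") {
    ht <- t.test(a, b, var.equal = var_equal)
    list(statistic = unname(ht$statistic), p_value = ht$p.value, test = "t",
         mean_a = mean(a), mean_b = mean(b))
  } else {
    ht <- wilcox.test(a, b, exact = NULL)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "mann-whitney", mean_a = mean(a), mean_b = mean(b))
  }
}

#' Kruskal-Wallis with Dunn's pairwise comparisons across metrics
#'
#' Tests whether different wheel metrics (e.g. distance, time, average
#' speed) detect the 20\% decline at different ages: a tie-corrected
#' Kruskal-Wallis H across the groups followed by Dunn's pairwise z
#' statistics on the pooled ranks, with a Bonferroni correction across the
#' pairs.
#'
#' @param x a named list of numeric vectors (one per metric/group), or a
#'   data frame with columns `metric` and `onset_age`.
#' @return List: `H`, `df`, `p_value`, and `dunn`, a data frame with one row
#'   per pair (`z`, `p_unadjusted`, `p_adjusted`).
#' @export
rank_compare_metrics <- function(x) {
  if (is.data.frame(x))
    x <- split(x$onset_age, x$metric)
  x <- lapply(x, function(v) v[!is.na(v)])
  if (length(x) < 2 || any(lengths(x) < 2))
    stop("need >= 2 groups with >= 2 values each")
  k <- length(x)
  g <- factor(rep(names(x), lengths(x)), levels = names(x))
  v <- unlist(x, use.names = FALSE)
  kw <- kruskal.test(v, g)

  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  n <- lengths(x)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(names(x), 2)
  z <- apply(pairs, 2, function(p)
    (rbar[[p[1]]] - rbar[[p[2]]]) /
      sqrt(sigma2 * (1 / n[[p[1]]] + 1 / n[[p[2]]])))
  p_un <- 2 * pnorm(-abs(z))
  dunn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                     p_unadjusted = p_un,
                     p_adjusted = pmin(1, p_un * ncol(pairs)))
  rownames(dunn) <- NULL
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, dunn = dunn)
}

#' Published multi-study onset summaries
#'
#' The per-study summaries of the age at 20\% reduction in running-wheel
#' activity for seven placebo/control SOD1-G93A cohorts run over 18 months
#' (the initial cohort plus six subsequent therapeutic-study placebo arms),
#' as printed: per study and metric, N, mean onset age, SD, and the printed
#' CV.  The `"All"` row pools the 71 tabulated mice.  These feed the
#' reproducibility (within- and between-study CV) and power analyses.
#'
#' @return A data frame with columns `study_id`, `n`, `metric`,
#'   `mean_onset`, `sd_onset`, `cv_printed`.
#' @export
reference_onset_summaries <- function() {
  studies <- c("1", "2", "3", "4", "5", "6", "7", "All")
  n <- c(15, 8, 9, 7, 6, 12, 14, 71)
  dist_m <- c(44.27, 41.75, 43.22, 44.71, 44.67, 45.21, 42.86, 43.85)
  dist_s <- c(3.31, 3.28, 4.44, 5.44, 4.23, 3.40, 4.09, 3.93)
  dist_cv <- c(7.4, 7.9, 10.3, 12.2, 9.5, 7.5, 9.5, 9.0)
  time_m <- c(45.57, 43.13, 44.56, 44.29, 45.00, 46.07, 43.93, 44.77)
  time_s <- c(4.54, 3.98, 3.40, 9.62, 3.69, 3.79, 5.02, 4.84)
  time_cv <- c(10.0, 9.2, 7.6, 21.7, 8.2, 8.2, 11.4, 10.8)
  sp_m <- c(47.13, 43.38, 48.25, 45.80, 46.00, 46.42, 48.67, 46.77)
  sp_s <- c(3.76, 4.34, 5.80, 1.92, 5.10, 2.31, 4.52, 4.21)
  sp_cv <- c(8.0, 10.0, 12.0, 4.2, 11.1, 5.0, 9.3, 9.0)
  rbind(
    data.frame(study_id = studies, n = n, metric = "distance",
               mean_onset = dist_m, sd_onset = dist_s, cv_printed = dist_cv),
    data.frame(study_id = studies, n = n, metric = "time",
               mean_onset = time_m, sd_onset = time_s, cv_printed = time_cv),
    data.frame(study_id = studies, n = n, metric = "avg_speed",
               mean_onset = sp_m, sd_onset = sp_s, cv_printed = sp_cv))
}
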