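#' Default CTCAE-style ANC thresholds
#'
#' Grade 3: ANC below 1E9 cells/L; grade 4: below 5E8; recovery requires
#' an ANC above the grade-2 threshold (1.5E9, CTCAE convention).
#'
#' @return Named numeric vector `(grade3, grade4, grade2)` in cells/L.
#' @export
default_thresholds <- function() {
  c(grade3 = 1e9, grade4 = 5e8, grade2 = 1.5e9)
}

#' Daily ANC reduction of an hourly trajectory
#'
#' Day `d` covers hours `[24(d-1), 24d]`; the daily ANC is the minimum of
#' the simulated hourly ANC within the day (a conservative day-granular
#' reduction).  Restricted to the first 28 days (cycle 1).
#'
#' @param series An `anc_series`, or a numeric vector already holding
#'   daily values (returned unchanged, truncated to 28 days).
#' @param n_days Number of days to reduce to (default 28).
#' @return Numeric vector of daily ANC values (cells/L), one per day.
#' @export
daily_anc <- function(series, n_days = 28) {
  if (is.numeric(series)) return(utils::head(series, n_days))
  stopifnot(inherits(series, "anc_series"))
  if (length(series$times) == 0) stop("empty ANC series")
  n <- min(n_days, floor(max(series$times) / 24))
  vapply(seq_len(n), function(d) {
    sel <- series$times >= 24 * (d - 1) & series$times <= 24 * d
    min(series$anc[sel])
  }, numeric(1))
}

#' Below-threshold toxicity events of an ANC trajectory
#'
#' Maximal runs of consecutive days whose daily ANC is below the
#' threshold, within the first 28 days.
#'
#' @param series An `anc_series` or a daily ANC vector (see
#'   [daily_anc()]).
#' @param threshold Toxicity threshold (cells/L), e.g. 1e9 for grade 3.
#' @return Data frame with one row per event: `start_day`, `end_day`
#'   (inclusive, 1-based) and `duration_days`.
#' @examples
#' grade_events(c(4.5, 2, 0.9, 0.8, 1.2, 1.6) * 1e9, 1e9)  # days 3-4
#' @export
grade_events <- function(series, threshold) {
  d <- daily_anc(series)
  if (length(d) == 0) stop("empty ANC series")
  below <- d < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_day = starts[keep], end_day = ends[keep],
             duration_days = r$lengths[keep])
}

#' Recovery from a toxicity event
#'
#' A patient recovered if, after the first toxicity onset, at least one
#' daily ANC within cycle 1 rises above the grade-2 threshold.  Time to
#' recovery is counted from first onset to the first such day.
#'
#' @param series An `anc_series` or daily ANC vector.
#' @param events Event table from [grade_events()]; must be non-empty.
#' @param grade2_threshold Recovery threshold (cells/L), default 1.5e9.
#' @return List with `recovered` (logical) and `time_to_recovery` (days;
#'   NA when not recovered).
#' @export
recovery <- function(series, events, grade2_threshold = 1.5e9) {
  if (nrow(events) == 0) stop("recovery requires at least one event")
  d <- daily_anc(series)
  onset <- min(events$start_day)
  after <- which(seq_along(d) > onset & d > grade2_threshold)
  if (length(after) == 0)
    list(recovered = FALSE, time_to_recovery = NA_real_)
  else
    list(recovered = TRUE, time_to_recovery = min(after) - onset)
}

#' Day of the ANC nadir within cycle 1
#'
#' @param series An `anc_series` or daily ANC vector.
#' @return Day index (1-28) of the minimum daily ANC; ties broken to the
#'   earliest day.
#' @export
time_to_nadir <- function(series) {
  d <- daily_anc(series)
  which.min(d)
}

#' Aggregate per-patient toxicity endpoints over a cohort
#'
#' Computes the incidence table used to contrast dose/schedule scenarios:
#' percentage of patients with at least one grade-3 and grade-4 event,
#' percentage with an uninterrupted event lasting at least 7 days,
#' percentage recovered above the grade-2 threshold (per grade, as a
#' percentage of the whole cohort), mean time to recovery over recovered
#' patients, and the time-to-nadir distribution.
#'
#' @param series_list List of `anc_series` (or daily ANC vectors).
#' @param thresholds Named vector with `grade3`, `grade4`, `grade2`
#'   (cells/L); default [default_thresholds()].
#' @param exposure Optional list with `auc_cycle1` and `cmax` from
#'   [exposure_metrics()], carried into the summary.
#' @return Object of class `cohort_toxicity_summary` (a list; see fields
#'   in the summary's print method), with `as.data.frame()` giving a
#'   single summary row.
#' @export
summarize_cohort <- function(series_list, thresholds = default_thresholds(),
                             exposure = NULL) {
  n <- length(series_list)
  if (n == 0) stop("summarize_cohort requires at least one series")
  per_grade <- function(thr) {
    single <- logical(n); seven <- logical(n); rec <- logical(n)
    ttr <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ev <- grade_events(series_list[[i]], thr)
      if (nrow(ev) == 0) next
      single[i] <- TRUE
      seven[i] <- any(ev$duration_days >= 7)
      r <- recovery(series_list[[i]], ev, thresholds[["grade2"]])
      rec[i] <- r$recovered
      ttr[i] <- r$time_to_recovery
    }
    list(single = 100 * mean(single), seven_day = 100 * mean(seven),
         recovered = 100 * mean(rec),
         mean_time_to_recovery = if (any(rec)) mean(ttr[rec]) else NA_real_)
  }
  g3 <- per_grade(thresholds[["grade3"]])
  g4 <- per_grade(thresholds[["grade4"]])
  structure(
    list(n = n,
         gr3_single_pct = g3$single, gr4_single_pct = g4$single,
         gr3_7day_pct = g3$seven_day, gr4_7day_pct = g4$seven_day,
         gr3_recovered_pct = g3$recovered, gr4_recovered_pct = g4$recovered,
         gr3_mean_time_to_recovery_days = g3$mean_time_to_recovery,
         gr4_mean_time_to_recovery_days = g4$mean_time_to_recovery,
         time_to_nadir_days = vapply(series_list, time_to_nadir, numeric(1)),
         auc_cycle1 = exposure$auc_cycle1, cmax = exposure$cmax,
         thresholds = thresholds),
    class = "cohort_toxicity_summary"
  )
}

#' @export
print.cohort_toxicity_summary <- function(x, ...) {
  cat(sprintf("Cohort toxicity summary (n = %d)\n", x$n))
  cat(sprintf("  grade 3: single %.1f%%, >=7 days %.1f%%, recovered %.1f%%\n",
              x$gr3_single_pct, x$gr3_7day_pct, x$gr3_recovered_pct))
  cat(sprintf("  grade 4: single %.1f%%, >=7 days %.1f%%, recovered %.1f%%\n",
              x$gr4_single_pct, x$gr4_7day_pct, x$gr4_recovered_pct))
  if (!is.null(x$auc_cycle1))
    cat(sprintf("  exposure: AUC %.4g ng/mL*h, Cmax %.4g ng/mL\n",
                x$auc_cycle1, x$cmax))
  cat(sprintf("  modal nadir day: %d\n", .modal_day(x$time_to_nadir_days)))
  invisible(x)
}

.modal_day <- function(days) {
  tab <- table(days)
  as.integer(names(tab)[which.max(tab)])
}

#' @export
as.data.frame.cohort_toxicity_summary <- function(x, ...) {
  data.frame(
    n = x$n,
    gr3_single_pct = x$gr3_single_pct, gr4_single_pct = x$gr4_single_pct,
    gr3_7day_pct = x$gr3_7day_pct, gr4_7day_pct = x$gr4_7day_pct,
    gr3_recovered_pct = x$gr3_recovered_pct,
    gr4_recovered_pct = x$gr4_recovered_pct,
    gr3_mean_ttr_days = .na_num(x$gr3_mean_time_to_recovery_days),
    gr4_mean_ttr_days = .na_num(x$gr4_mean_time_to_recovery_days),
    modal_nadir_day = .modal_day(x$time_to_nadir_days),
    auc_cycle1 = .na_num(x$auc_cycle1), cmax = .na_num(x$cmax)
  )
}

.na_num <- function(x) if (is.null(x)) NA_real_ else x

#' Dose-by-schedule virtual trial screen
#'
#' Simulates the same virtual cohort under every combination of dose and
#' schedule and scores each scenario, producing the dose/schedule summary
#' table used for toxicity screening.
#'
#' @param cohort A `virtual_cohort` or list of [patient_traits()]; the
#'   same patients are reused across all scenarios.
#' @param doses_mg Numeric vector of doses (mg).
#' @param schedules Character vector of `"on/period"` schedule strings
#'   (e.g. `"5/7"`, `"21/28"`).
#' @param pk,pd Model parameter objects.
#' @param thresholds Toxicity thresholds, see [summarize_cohort()].
#' @param horizon_days Simulation horizon (default 28).
#' @param exposure_pk Optional `pk_params` used for the reported AUC/Cmax
#'   columns (default: `pk`); evaluated on a 0.05 h analytic grid.
#' @param ... Passed to [simulate_patient()].
#' @return Data frame with one row per (dose, schedule) scenario: the
#'   summary columns of [summarize_cohort()] plus `dose_mg`, `schedule`,
#'   `n_doses`.
#' @export
scenario_grid <- function(cohort, doses_mg, schedules,
                          pk = default_pk_params(), pd = default_pd_params(),
                          thresholds = default_thresholds(),
                          horizon_days = 28, exposure_pk = pk, ...) {
  if (length(doses_mg) == 0 || length(schedules) == 0)
    stop("doses_mg and schedules must be non-empty")
  rows <- list()
  for (sched in schedules) {
    for (dose in doses_mg) {
      reg <- parse_regimen(sprintf("%gmg %s", dose, sched))
      sims <- tryCatch(
        simulate_cohort(cohort, pk = pk, pd = pd, reg = reg,
                        horizon_days = horizon_days, ...),
        error = function(e) stop("scenario ", dose, " mg ", sched, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      tfine <- seq(0, horizon_days * 24, by = 0.05)
      doses_t <- dosing_times(reg, horizon_days)
      expo <- exposure_metrics(
        tfine, pk_concentration(exposure_pk, doses_t, dose, tfine))
      row <- as.data.frame(summarize_cohort(sims, thresholds, expo))
      row$dose_mg <- dose
      row$schedule <- sched
      row$n_doses <- length(doses_t)
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[, c("dose_mg", "schedule", "n_doses",
          setdiff(names(out), c("dose_mg", "schedule", "n_doses")))]
}
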