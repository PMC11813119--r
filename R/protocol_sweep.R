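#' Median and quartiles of participant averages
#'
#' Quartile convention: linear interpolation between order statistics
#' (`stats::quantile` type 7), fixed and documented so sweep summaries are
#' comparable across runs.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
quantile_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values))) {
    stop_domain("quantile_summary needs a non-empty collection")
  }
  q <- quantile(values, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7,
                names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' One setting of a trigger-rule sweep
#'
#' @param label Unique label within the sweep (e.g. `"Original"`,
#'   `"Duration 20"`).
#' @param rule An [event_rule()].
#' @param constraints A [schedule_constraints()].
#' @return A `sweep_setting` list.
#' @export
sweep_setting <- function(label, rule, constraints) {
  structure(list(label = label, rule = rule, constraints = constraints),
            class = "sweep_setting")
}

sedentary_constraints <- function(backwards_span_min = 1L) {
  schedule_constraints(
    backwards_span_min, min_interval_min = 90L, daily_cap = 4,
    windows = tibble(start = c("08:00", "14:00"),
                     end = c("14:00", "20:00"), cap = c(2, 2))
  )
}

walking_constraints <- function(backwards_span_min = 2L) {
  schedule_constraints(backwards_span_min, min_interval_min = 90L,
                       daily_cap = 3)
}

#' Standard sedentary sweep grid
#'
#' The sedentary setting grid: the original 30-minute zero-step rule with a
#' 1-minute backwards span, then single relaxations (backwards span 17, one
#' tolerated outlier minute, duration 20), and the optimal setting (identical
#' to "Duration 20"). All settings require a heart-rate sample every minute,
#' use a 90-minute refractory interval, and fire only inside the 08:00–14:00
#' and 14:00–20:00 windows (2 triggers each).
#'
#' @return List of [sweep_setting()]s.
#' @export
sedentary_sweep_settings <- function() {
  sed_rule <- function(duration, outliers = 0L) {
    event_rule("sedentary", duration, 0, 0, outliers,
               if (outliers > 0) "above_high" else "none",
               require_hr_each_minute = TRUE)
  }
  list(
    sweep_setting("Original", sed_rule(30), sedentary_constraints(1)),
    sweep_setting("Backwards 17", sed_rule(30), sedentary_constraints(17)),
    sweep_setting("Outlier 1", sed_rule(30, 1), sedentary_constraints(1)),
    sweep_setting("Duration 20", sed_rule(20), sedentary_constraints(1)),
    sweep_setting("Optimal", sed_rule(20), sedentary_constraints(1))
  )
}

#' Standard walking sweep grid
#'
#' The walking setting grid: the original 10-minute 60–139 steps/min rule with
#' 2 above-threshold outliers and a 2-minute backwards span; single
#' relaxations (backwards span 17, outliers below the threshold, duration 5);
#' and the optimal setting combining duration 5, below-threshold outliers, and
#' backwards span 17. All settings cap walking triggers at 3/day with a
#' 90-minute refractory interval.
#'
#' @return List of [sweep_setting()]s.
#' @export
walking_sweep_settings <- function() {
  walk_rule <- function(duration, direction) {
    event_rule("walking", duration, 60, 139, 2L, direction)
  }
  list(
    sweep_setting("Original", walk_rule(10, "above_high"),
                  walking_constraints(2)),
    sweep_setting("Backwards 17", walk_rule(10, "above_high"),
                  walking_constraints(17)),
    sweep_setting("Outliers below", walk_rule(10, "below_low"),
                  walking_constraints(2)),
    sweep_setting("Duration 5", walk_rule(5, "above_high"),
                  walking_constraints(2)),
    sweep_setting("Optimal", walk_rule(5, "below_low"),
                  walking_constraints(17))
  )
}

#' Run a trigger-rule sweep over a cohort
#'
#' For each setting: detect bouts in every participant's stream, simulate
#' triggers under the setting's constraints and the sync model, count triggers
#' per valid day, average per participant over their valid days, and summarise
#' the participant means as median (IQR).
#'
#' @param cohort Named list of [ema_stream]s, normally already passed through
#'   [filter_simulation_cohort()].
#' @param settings List of [sweep_setting()]s with unique labels.
#' @param sync A [sync_model()] (default regular 15-minute syncs).
#' @param valid_days_only Count triggers on (and divide by) valid days only
#'   (default `TRUE`); otherwise all study days.
#' @return Tibble with one row per setting: `label`, `median`, `q1`, `q3`,
#'   and a `per_participant` list-column of participant daily means.
#' @export
run_sweep <- function(cohort, settings, sync = sync_model(),
                      valid_days_only = TRUE) {
  if (length(cohort) == 0) stop_domain("empty cohort")
  labels <- vapply(settings, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_domain("sweep labels must be unique")
  purrr::map_dfr(settings, function(s) {
    per <- vapply(cohort, function(stream) {
      ds <- day_summary(stream)
      days <- if (valid_days_only) ds$date[ds$is_valid] else ds$date
      if (length(days) == 0) return(NA_real_)
      bouts <- find_bouts(stream, s$rule)
      trig <- simulate_event_triggers(
        setNames(list(bouts), s$rule$kind), sync,
        setNames(list(s$constraints), s$rule$kind),
        dates = stream$study_days, total_daily_cap = Inf
      )
      sum(civil_date(trig$fire_time) %in% days) / length(days)
    }, numeric(1))
    per <- per[!is.na(per)]
    qs <- quantile_summary(per)
    tibble(label = s$label, median = qs[["median"]], q1 = qs[["q1"]],
           q3 = qs[["q3"]], per_participant = list(per))
  })
}

#' Write a sweep summary as a table-shaped CSV
#'
#' Columns mirror the published sweep tables: setting label, event duration,
#' threshold, outliers, backwards span, and the median (IQR) of triggers/day.
#'
#' @param summary Output of [run_sweep()].
#' @param settings The settings list the summary was computed from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(summary, settings, path) {
  meta <- purrr::map_dfr(settings, function(s) {
    r <- s$rule
    thr <- if (r$step_low == r$step_high) sprintf("= %g", r$step_low)
      else if (is.infinite(r$step_high)) sprintf(">= %g", r$step_low)
      else sprintf("%g to %g", r$step_low, r$step_high)
    tibble(
      label = s$label,
      event_duration_min = r$duration_min,
      threshold_steps = thr,
      outliers = if (r$outlier_allowance == 0) "0" else
        sprintf("%d (%s)", r$outlier_allowance,
                if (r$outlier_direction == "above_high") "above" else "below"),
      backwards_min = s$constraints$backwards_span_min
    )
  })
  out <- dplyr::left_join(meta, summary[, c("label", "median", "q1", "q3")],
                          by = "label")
  out$triggers_median_iqr <- sprintf("%.2f (%.2f-%.2f)", out$median, out$q1,
                                     out$q3)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
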