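#' Define an event-detection rule
#'
#' An event rule describes the bouts that should trigger a survey: a window of
#' `duration_min` consecutive minutes whose step counts fall inside
#' `[step_low, step_high]`, with up to `outlier_allowance` violating minutes
#' tolerated, and only in one direction (`above_high` or `below_low`). The
#' first and last minutes of a window must always satisfy the bounds, so a
#' bout can neither start nor end on an outlier. Sedentary rules additionally
#' require at least one heart-rate sample in every minute of the window
#' ("zero steps while worn"), which also excludes unrecorded minutes.
#'
#' @param kind One of `"sedentary"`, `"walking"`, `"running"`.
#' @param duration_min Window length in minutes (>= 1).
#' @param step_low,step_high Inclusive step bounds per minute; `NULL` means
#'   unbounded on that side (running uses `step_high = NULL`).
#' @param outlier_allowance Number of tolerated violating minutes
#'   (< `duration_min`).
#' @param outlier_direction `"none"`, `"above_high"` or `"below_low"`;
#'   `"none"` if and only if `outlier_allowance == 0`.
#' @param require_hr_each_minute Require `hr_samples >= 1` in every minute of
#'   the window (wear control).
#' @return An object of class `ema_rule`.
#' @export
#' @examples
#' # the original Germany/Czechia sedentary rule
#' event_rule("sedentary", 30, 0, 0, require_hr_each_minute = TRUE)
event_rule <- function(kind, duration_min, step_low = NULL, step_high = NULL,
                       outlier_allowance = 0L,
                       outlier_direction = c("none", "above_high", "below_low"),
                       require_hr_each_minute = FALSE) {
  kind <- match.arg(kind, c("sedentary", "walking", "running"))
  outlier_direction <- match.arg(outlier_direction)
  duration_min <- as.integer(duration_min)
  outlier_allowance <- as.integer(outlier_allowance)
  if (duration_min < 1) stop_domain("duration_min must be >= 1")
  if (outlier_allowance >= duration_min) {
    stop_domain("outlier_allowance must be smaller than duration_min")
  }
  if ((outlier_direction == "none") != (outlier_allowance == 0L)) {
    stop_domain("outlier_direction is 'none' exactly when outlier_allowance is 0")
  }
  structure(
    list(kind = kind, duration_min = duration_min,
         step_low = if (is.null(step_low)) -Inf else as.numeric(step_low),
         step_high = if (is.null(step_high)) Inf else as.numeric(step_high),
         outlier_allowance = outlier_allowance,
         outlier_direction = outlier_direction,
         require_hr_each_minute = isTRUE(require_hr_each_minute)),
    class = "ema_rule"
  )
}

#' @export
print.ema_rule <- function(x, ...) {
  cat(sprintf(
    "<ema_rule> %s: %d min, steps in [%s, %s], %d outlier(s) %s%s\n",
    x$kind, x$duration_min,
    format(x$step_low), format(x$step_high),
    x$outlier_allowance,
    x$outlier_direction,
    if (x$require_hr_each_minute) ", HR required every minute" else ""
  ))
  invisible(x)
}

empty_bouts <- function(kind) {
  tibble(
    start_minute = as.POSIXct(character(), tz = .EMASIM_TZ),
    end_minute = as.POSIXct(character(), tz = .EMASIM_TZ),
    kind = character(), n_outliers = integer()
  )
}

as_epochs <- function(stream) {
  if (inherits(stream, "ema_stream")) stream$epochs else as_tibble(stream)
}

# Per-minute classification shared by detection and its oracle's *inputs*
# (the oracle re-derives the predicate per window from raw steps/hr).
# Unrecorded minutes behave as steps = 0, hr_samples = 0.
classify_minutes <- function(grid, rule) {
  in_bounds <- grid$steps >= rule$step_low & grid$steps <= rule$step_high
  viol <- !in_bounds
  allowed <- switch(rule$outlier_direction,
    none = rep(FALSE, nrow(grid)),
    above_high = grid$steps > rule$step_high,
    below_low = grid$steps < rule$step_low
  )
  list(ok = in_bounds, viol = viol, bad = viol & !allowed,
       hr_ok = grid$hr_samples >= 1L)
}

#' Find qualifying bouts under a rule
#'
#' Scans a minute-epoch stream and returns one bout per qualifying end-minute:
#' every window of `duration_min` consecutive clock minutes in which at most
#' `outlier_allowance` minutes violate the step bounds (and only in the
#' permitted direction), the first and last minutes satisfy the bounds, and —
#' when the rule requires it — every minute has at least one heart-rate
#' sample. Minutes absent from the stream are treated as zero steps with no
#' heart-rate sample.
#'
#' @param stream An [ema_stream] or a data frame of epochs
#'   (`minute_start`, `steps`, `hr_samples`), sorted and duplicate-free.
#' @param rule An [event_rule()].
#' @return A tibble of bouts ordered by `end_minute`, with columns
#'   `start_minute`, `end_minute` (the start of the last included minute),
#'   `kind`, `n_outliers`.
#' @export
find_bouts <- function(stream, rule) {
  ep <- as_epochs(stream)
  if (nrow(ep) > 1 && any(diff(as.numeric(ep$minute_start)) <= 0)) {
    stop_domain("stream epochs must be sorted and duplicate-free")
  }
  d <- rule$duration_min
  if (nrow(ep) < 1) return(empty_bouts(rule$kind))
  grid <- minute_grid(ep)
  n <- nrow(grid)
  if (n < d) return(empty_bouts(rule$kind))

  cl <- classify_minutes(grid, rule)
  # rolling window sums via cumulative sums; window i covers [i, i + d - 1]
  csum <- function(x) {
    cs <- cumsum(x)
    cs[d:n] - c(0, cs)[(d:n) - d + 1]
  }
  n_viol <- csum(cl$viol)
  n_bad <- csum(cl$bad)
  starts <- 1:(n - d + 1)
  ends <- starts + d - 1L
  qual <- n_bad == 0 & n_viol <= rule$outlier_allowance &
    cl$ok[starts] & cl$ok[ends]
  if (rule$require_hr_each_minute) {
    qual <- qual & csum(cl$hr_ok) == d
  }
  if (!any(qual)) return(empty_bouts(rule$kind))
  tibble(
    start_minute = grid$minute_start[starts[qual]],
    end_minute = grid$minute_start[ends[qual]],
    kind = rule$kind,
    n_outliers = as.integer(n_viol[qual])
  )
}

#' Exhaustive reference bout finder
#'
#' Same contract as [find_bouts()], implemented by checking every window of
#' `duration_min` minutes directly against the rule, one window at a time.
#' Intended as an independent oracle in tests; quadratic and slow on long
#' streams.
#'
#' @inheritParams find_bouts
#' @return As [find_bouts()].
#' @export
brute_force_bouts <- function(stream, rule) {
  ep <- as_epochs(stream)
  if (nrow(ep) > 1 && any(diff(as.numeric(ep$minute_start)) <= 0)) {
    stop_domain("stream epochs must be sorted and duplicate-free")
  }
  d <- rule$duration_min
  if (nrow(ep) < 1) return(empty_bouts(rule$kind))
  grid <- minute_grid(ep)
  n <- nrow(grid)
  out <- list()
  for (i in seq_len(max(0, n - d + 1))) {
    w <- i:(i + d - 1)
    steps <- grid$steps[w]
    hr <- grid$hr_samples[w]
    inb <- steps >= rule$step_low & steps <= rule$step_high
    n_viol <- sum(!inb)
    if (n_viol > rule$outlier_allowance) next
    if (!inb[1] || !inb[d]) next
    if (n_viol > 0) {
      dir_ok <- switch(rule$outlier_direction,
        none = FALSE,
        above_high = all(steps[!inb] > rule$step_high),
        below_low = all(steps[!inb] < rule$step_low)
      )
      if (!dir_ok) next
    }
    if (rule$require_hr_each_minute && any(hr < 1)) next
    out[[length(out) + 1]] <- tibble(
      start_minute = grid$minute_start[i],
      end_minute = grid$minute_start[i + d - 1],
      kind = rule$kind,
      n_outliers = n_viol
    )
  }
  if (length(out) == 0) return(empty_bouts(rule$kind))
  dplyr::bind_rows(out)
}
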