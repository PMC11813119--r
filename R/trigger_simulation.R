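#' Device sync model
#'
#' The wearable uploads its minute data only periodically (nominally every 15
#' minutes), so event-based surveys can fire only at sync times. `regular`
#' gives syncs at `offset, offset + period, ...` within each day; `jittered`
#' perturbs each sync by a uniform amount up to `jitter_min` minutes.
#'
#' @param period_min Sync period in minutes (default 15).
#' @param offset_min Offset of the first daily sync within `[0, period)`.
#' @param mode `"regular"` or `"jittered"`.
#' @param jitter_min Maximum absolute jitter in minutes (jittered mode only).
#' @return An object of class `ema_sync`.
#' @export
sync_model <- function(period_min = 15L, offset_min = 0L,
                       mode = c("regular", "jittered"), jitter_min = 3) {
  mode <- match.arg(mode)
  period_min <- as.integer(period_min)
  if (period_min < 1) stop_domain("period_min must be >= 1")
  if (offset_min < 0 || offset_min >= period_min) {
    stop_domain("offset_min must lie in [0, period_min)")
  }
  structure(list(period_min = period_min, offset_min = as.integer(offset_min),
                 mode = mode, jitter_min = jitter_min),
            class = "ema_sync")
}

#' Scheduling constraints for one event kind
#'
#' @param backwards_span_min How far (minutes) before a sync a bout's
#'   end-minute may lie and still fire at that sync (1, 2, or 17 in the
#'   shipped presets).
#' @param min_interval_min Refractory period between two triggers of the same
#'   kind, in minutes (default 90); enforced across the whole timeline, not
#'   reset at midnight.
#' @param daily_cap Maximum triggers of this kind per day.
#' @param windows Optional data frame of daily firing windows with columns
#'   `start`, `end` (`"HH:MM"` strings, half-open `[start, end)`) and `cap`
#'   (max triggers inside the window per day). Windows must not overlap.
#'   Windows constrain the fire time, not the bout location.
#' @return An object of class `ema_constraints`.
#' @export
schedule_constraints <- function(backwards_span_min, min_interval_min = 90L,
                                 daily_cap = Inf, windows = NULL) {
  if (backwards_span_min < 1) stop_domain("backwards_span_min must be >= 1")
  if (!is.null(windows)) {
    windows <- as_tibble(windows)
    stopifnot(all(c("start", "end", "cap") %in% names(windows)))
    w <- tibble(start_min = hm_to_min(windows$start),
                end_min = hm_to_min(windows$end),
                cap = as.numeric(windows$cap))
    w <- w[order(w$start_min), ]
    if (any(w$end_min <= w$start_min)) stop_format("window end must be after start")
    if (nrow(w) > 1 && any(w$start_min[-1] < w$end_min[-nrow(w)])) {
      stop_format("constraint windows must not overlap")
    }
    if (any(w$cap < 0)) stop_domain("window caps must be >= 0")
    windows <- w
  }
  structure(list(backwards_span_min = as.integer(backwards_span_min),
                 min_interval_min = as.integer(min_interval_min),
                 daily_cap = daily_cap, windows = windows),
            class = "ema_constraints")
}

#' Prompt lifecycle parameters
#'
#' @param reminder_offsets_min Minutes after the prompt at which reminders are
#'   sent if the survey has not been started (default 3, 6, 7).
#' @param expiry_min Minutes after which an unanswered survey expires
#'   (default 8; 15 is a common relaxation).
#' @return An object of class `ema_lifecycle`.
#' @export
prompt_lifecycle <- function(reminder_offsets_min = c(3, 6, 7), expiry_min = 8) {
  if (any(reminder_offsets_min >= expiry_min)) {
    stop_domain("reminders must fall strictly before expiry")
  }
  structure(list(reminder_offsets_min = sort(reminder_offsets_min),
                 expiry_min = expiry_min),
            class = "ema_lifecycle")
}

#' Load a shipped protocol preset
#'
#' Presets bundle the sync model, prompt lifecycle, per-kind event rules and
#' scheduling constraints, and the joint daily event cap. Shipped presets:
#' `"cz_de_original"`, `"ie_fr_relaxed"`, `"optimal"`.
#'
#' @param name Preset name, or a path to a preset JSON file.
#' @return A list with elements `name`, `sync` ([sync_model()]), `lifecycle`
#'   ([prompt_lifecycle()]), `rules` (named list of [event_rule()]),
#'   `constraints` (named list of [schedule_constraints()]) and
#'   `total_daily_cap`.
#' @export
#' @examples
#' p <- ema_preset("ie_fr_relaxed")
#' p$rules$sedentary
ema_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".json"), package = "emasim")
  if (!nzchar(path) || !file.exists(path)) {
    stop_format(sprintf("unknown preset '%s'", name))
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(raw$rules, function(r) {
    event_rule(r$kind, r$duration_min, r$step_low, r$step_high,
               r$outlier_allowance, r$outlier_direction,
               isTRUE(r$require_hr_each_minute))
  })
  constraints <- lapply(raw$constraints, function(cst) {
    windows <- NULL
    if (!is.null(cst$windows)) {
      windows <- purrr::map_dfr(cst$windows, as_tibble)
    }
    schedule_constraints(cst$backwards_span_min, cst$min_interval_min,
                         cst$daily_cap %||% Inf, windows)
  })
  list(
    name = raw$name,
    sync = sync_model(raw$sync$period_min, raw$sync$offset_min, raw$sync$mode),
    lifecycle = prompt_lifecycle(unlist(raw$lifecycle$reminder_offsets_min),
                                 raw$lifecycle$expiry_min),
    rules = rules,
    constraints = constraints,
    total_daily_cap = raw$total_daily_cap %||% Inf
  )
}

#' Sync times on a date
#'
#' @param sync A [sync_model()].
#' @param date Civil date.
#' @param seed Optional seed for jittered mode.
#' @return Ordered POSIXct vector of sync times within the date.
#' @export
sync_times <- function(sync, date, seed = NULL) {
  date <- as.Date(date)
  mins <- seq(sync$offset_min, 1439L, by = sync$period_min)
  if (sync$mode == "jittered") {
    if (!is.null(seed)) set.seed(seed)
    mins <- mins + runif(length(mins), -sync$jitter_min, sync$jitter_min)
    mins <- sort(pmin(pmax(mins, 0), 1439.99))
  }
  day_minute(date, mins)
}

window_index <- function(mod, windows) {
  # index of the half-open [start, end) window containing minute-of-day `mod`
  hit <- which(mod >= windows$start_min & mod < windows$end_min)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Simulate event-based triggers over a date range
#'
#' Replays the trigger engine against detected bouts: syncs are processed
#' chronologically and at each sync, for each kind (sedentary, then walking,
#' then running), the most recent unconsumed bout whose end-minute lies within
#' the backwards span fires a trigger provided the kind's refractory interval,
#' its window cap and daily cap, and the joint daily event cap all allow it.
#' Each bout fires at most once; a consumed bout never re-fires.
#'
#' @param bouts_by_kind Named list of bout tibbles from [find_bouts()], one
#'   per kind (missing kinds are treated as empty).
#' @param sync A [sync_model()].
#' @param constraints Named list of [schedule_constraints()], one per kind in
#'   `bouts_by_kind`.
#' @param dates Civil dates to simulate (syncs are generated for each).
#' @param total_daily_cap Joint cap on event-based triggers per day across all
#'   kinds (default 10).
#' @param seed Optional seed (jittered sync mode only).
#' @return Tibble of triggers ordered by `fire_time`: `fire_time`, `kind`,
#'   `bout_end`, `delay_min` (minutes from the start of the bout's last minute
#'   to the fire time; at most the backwards span).
#' @export
simulate_event_triggers <- function(bouts_by_kind, sync, constraints, dates,
                                    total_daily_cap = 10, seed = NULL) {
  kinds <- intersect(c("sedentary", "walking", "running"),
                     union(names(bouts_by_kind), names(constraints)))
  dates <- sort(as.Date(dates))
  syncs <- do.call(c, lapply(seq_along(dates), function(i) {
    sync_times(sync, dates[i], seed = if (is.null(seed)) NULL else seed + i)
  }))
  syncs_num <- as.numeric(syncs)

  state <- list()
  for (k in kinds) {
    b <- bouts_by_kind[[k]]
    ends <- if (is.null(b) || nrow(b) == 0) numeric(0) else
      sort(as.numeric(b$end_minute))
    state[[k]] <- list(ends = ends, consumed = rep(FALSE, length(ends)),
                       last_fire = -Inf)
  }

  out_time <- numeric(0); out_kind <- character(0)
  out_bout <- numeric(0); out_delay <- numeric(0)

  cur_day <- as.Date(NA)
  day_counts <- setNames(numeric(length(kinds)), kinds)
  day_total <- 0
  win_counts <- lapply(kinds, function(k) {
    w <- constraints[[k]]$windows
    if (is.null(w)) NULL else numeric(nrow(w))
  })
  names(win_counts) <- kinds

  for (i in seq_along(syncs_num)) {
    t <- syncs_num[i]
    t_day <- civil_date(syncs[i])
    if (is.na(cur_day) || t_day != cur_day) {
      cur_day <- t_day
      day_counts[] <- 0
      day_total <- 0
      for (k in kinds) {
        if (!is.null(win_counts[[k]])) win_counts[[k]][] <- 0
      }
    }
    mod <- (t %% 86400) / 60
    for (k in kinds) {
      cst <- constraints[[k]]
      st <- state[[k]]
      if (length(st$ends) == 0) next
      if (day_total >= total_daily_cap) break
      if (day_counts[[k]] >= cst$daily_cap) next
      if (t - st$last_fire < cst$min_interval_min * 60) next
      widx <- NA_integer_
      if (!is.null(cst$windows)) {
        widx <- window_index(mod, cst$windows)
        if (is.na(widx)) next
        if (win_counts[[k]][widx] >= cst$windows$cap[widx]) next
      }
      # most recent unconsumed bout with end-minute in [t - span, t)
      lo <- t - cst$backwards_span_min * 60
      cand <- which(st$ends >= lo & st$ends < t & !st$consumed)
      if (length(cand) == 0) next
      j <- max(cand)
      state[[k]]$consumed[j] <- TRUE
      state[[k]]$last_fire <- t
      day_counts[[k]] <- day_counts[[k]] + 1
      day_total <- day_total + 1
      if (!is.na(widx)) win_counts[[k]][widx] <- win_counts[[k]][widx] + 1
      out_time <- c(out_time, t)
      out_kind <- c(out_kind, k)
      out_bout <- c(out_bout, st$ends[j])
      out_delay <- c(out_delay, (t - st$ends[j]) / 60)
    }
  }
  tibble(
    fire_time = as.POSIXct(out_time, origin = "1970-01-01", tz = .EMASIM_TZ),
    kind = out_kind,
    bout_end = as.POSIXct(out_bout, origin = "1970-01-01", tz = .EMASIM_TZ),
    delay_min = out_delay
  )
}

#' Default time-based survey windows
#'
#' The seven daily frames: morning 06:00–09:45, five daytime frames
#' (10:15–11:45, 12:15–13:45, 14:15–15:45, 16:15–17:45, 18:15–19:45) and
#' evening 20:15–22:00. Both endpoints are eligible prompt minutes, so the
#' smallest possible gap between two prompts is the 30-minute separation of
#' consecutive frames.
#'
#' @return Tibble with columns `label`, `start`, `end` (`"HH:MM"`).
#' @export
time_based_windows <- function() {
  tibble(
    label = c("morning", "daily1", "daily2", "daily3", "daily4", "daily5",
              "evening"),
    start = c("06:00", "10:15", "12:15", "14:15", "16:15", "18:15", "20:15"),
    end = c("09:45", "11:45", "13:45", "15:45", "17:45", "19:45", "22:00")
  )
}

#' Pre-schedule time-based surveys for a study period
#'
#' Draws one uniformly random prompt minute per window per day, for all days
#' up-front (the live system pre-schedules the whole study so the prompts fire
#' even without connectivity).
#'
#' @param dates Civil dates of the study period.
#' @param windows Window definition as from [time_based_windows()].
#' @param seed Seed for the draws.
#' @return Tibble `date`, `window` (label), `survey_type` (`morning`, `daily`,
#'   `evening`), `prompt_time`, 7 rows per day.
#' @export
schedule_time_based <- function(dates, windows = time_based_windows(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- sort(as.Date(dates))
  w_start <- hm_to_min(windows$start)
  w_end <- hm_to_min(windows$end)
  purrr::map_dfr(dates, function(d) {
    mins <- w_start + floor(runif(length(w_start)) * (w_end - w_start + 1))
    tibble(
      date = d,
      window = windows$label,
      survey_type = gsub("[0-9]+$", "", windows$label),
      prompt_time = day_minute(d, mins)
    )
  })
}

#' Walk a prompt through its reminder/expiry lifecycle
#'
#' @param prompt_time POSIXct prompt time.
#' @param lifecycle A [prompt_lifecycle()].
#' @param latency_s Seconds from prompt to response start, or `NA` if never
#'   answered. A start at or after expiry is rejected as unanswered.
#' @return A one-row tibble: `prompt_time`, `answered`, `start_time`,
#'   `expired_time` (`NA` when answered), `n_reminders`, and `reminder_times`
#'   (list-column of POSIXct reminders actually sent before the response).
#' @export
apply_lifecycle <- function(prompt_time, lifecycle, latency_s = NA_real_) {
  expiry_s <- lifecycle$expiry_min * 60
  answered <- !is.na(latency_s) && latency_s < expiry_s
  rem_off <- lifecycle$reminder_offsets_min * 60
  sent <- if (answered) rem_off[rem_off < latency_s] else rem_off
  tibble(
    prompt_time = prompt_time,
    answered = answered,
    start_time = if (answered) prompt_time + latency_s else
      as.POSIXct(NA, tz = .EMASIM_TZ),
    expired_time = if (answered) as.POSIXct(NA, tz = .EMASIM_TZ) else
      prompt_time + expiry_s,
    n_reminders = length(sent),
    reminder_times = list(prompt_time + sent)
  )
}
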