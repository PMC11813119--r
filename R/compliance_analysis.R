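#' Summarise compliance outcomes as median (IQR) of participant averages
#'
#' For each survey-type group, computes each participant's average prompts per
#' day, response rate, latency, and completion time, then the median and
#' interquartile range of those averages across participants. Latency and
#' completion are averaged over answered prompts only.
#'
#' @param records Prompt-record tibble (see [simulate_responses()]):
#'   `participant_id`, `day_index`, `survey_type`, `answered`, `latency_s`,
#'   `completion_s`.
#' @param groups Named list mapping group label to the survey types it pools;
#'   `NULL` (default) uses `all`, `time_based`, `event_based`, and each event
#'   type present. Groups with zero prompts are dropped with a warning.
#' @param days Number of study days for the per-day denominator; default
#'   `max(records$day_index)`.
#' @return Tibble with one row per group and columns `group`,
#'   `n_participants`, and `<metric>_median`, `<metric>_q1`, `<metric>_q3` for
#'   `prompts_per_day`, `response_rate`, `latency_s`, `completion_s`.
#' @export
summarise_compliance <- function(records, groups = NULL, days = NULL) {
  records <- as_tibble(records)
  if (nrow(records) == 0) stop_domain("no prompt records supplied")
  days <- days %||% max(records$day_index)
  if (is.null(groups)) {
    present <- unique(records$survey_type)
    groups <- list(all = present)
    if (any(c("morning", "daily", "evening") %in% present)) {
      groups$time_based <- c("morning", "daily", "evening")
    }
    if (any(c("sedentary", "walking", "running") %in% present)) {
      groups$event_based <- c("sedentary", "walking", "running")
    }
    for (k in intersect(c("sedentary", "walking", "running"), present)) {
      groups[[k]] <- k
    }
  }
  purrr::map_dfr(names(groups), function(g) {
    sub <- records[records$survey_type %in% groups[[g]], ]
    if (nrow(sub) == 0) {
      warn(sprintf("group '%s' has no prompts; excluded", g))
      return(NULL)
    }
    per <- sub |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(
        prompts_per_day = dplyr::n() / days,
        response_rate = mean(.data$answered),
        latency_s = mean(.data$latency_s[.data$answered]),
        completion_s = mean(.data$completion_s[.data$answered]),
        .groups = "drop"
      )
    q <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) return(c(NA_real_, NA_real_, NA_real_))
      unname(quantile_summary(x))
    }
    row <- tibble(group = g, n_participants = nrow(per))
    for (m in c("prompts_per_day", "response_rate", "latency_s",
                "completion_s")) {
      v <- q(per[[m]])
      row[[paste0(m, "_median")]] <- v[1]
      row[[paste0(m, "_q1")]] <- v[2]
      row[[paste0(m, "_q3")]] <- v[3]
    }
    row
  })
}

#' Fit a daily trend with a participant random intercept
#'
#' Models a compliance or reporting outcome against study day with a linear
#' mixed-effects model (`outcome ~ day_index + (1 | participant_id)`, REML),
#' the standard way to quantify habituation across a short EMA study. The
#' outcome is aggregated per participant-day first: response rate as the
#' percentage of prompts started, latency/completion as means over answered
#' prompts, meal counts as reports per day (days with no report count as
#' zero).
#'
#' @param records For `response_rate`, `latency`, `completion`: a
#'   prompt-record tibble. For `meal_count`: a meal-report tibble (see
#'   [simulate_meal_reports()]).
#' @param outcome One of `"response_rate"`, `"latency"`, `"completion"`,
#'   `"meal_count"`.
#' @param days For `meal_count`, the number of study days in the design
#'   (default `max(day_index)`).
#' @return An `ema_trend` object (list): `slope` (per day, in natural units —
#'   percentage points for response rate, seconds for times, reports for
#'   meals), `slope_se`, `p_value`, `model_desc`, `n_participants`, `n_days`,
#'   and the underlying `fit`.
#' @export
fit_daily_trend <- function(records,
                            outcome = c("response_rate", "latency",
                                        "completion", "meal_count"),
                            days = NULL) {
  outcome <- match.arg(outcome)
  records <- as_tibble(records)
  df <- switch(outcome,
    response_rate = records |>
      dplyr::group_by(.data$participant_id, .data$day_index) |>
      dplyr::summarise(y = 100 * mean(.data$answered), .groups = "drop"),
    latency = records |>
      dplyr::filter(.data$answered) |>
      dplyr::group_by(.data$participant_id, .data$day_index) |>
      dplyr::summarise(y = mean(.data$latency_s), .groups = "drop"),
    completion = records |>
      dplyr::filter(.data$answered) |>
      dplyr::group_by(.data$participant_id, .data$day_index) |>
      dplyr::summarise(y = mean(.data$completion_s), .groups = "drop"),
    meal_count = {
      days <- days %||% max(records$day_index)
      tidyr::expand_grid(participant_id = unique(records$participant_id),
                         day_index = seq_len(days)) |>
        dplyr::left_join(
          records |>
            dplyr::count(.data$participant_id, .data$day_index, name = "y"),
          by = c("participant_id", "day_index")
        ) |>
        dplyr::mutate(y = tidyr::replace_na(.data$y, 0L))
    }
  )
  if (dplyr::n_distinct(df$day_index) < 2) {
    stop_domain("trend fitting needs at least 2 distinct days")
  }
  if (dplyr::n_distinct(df$participant_id) < 2) {
    stop_domain("trend fitting needs at least 2 participants")
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ day_index + (1 | participant_id), data = df,
                   REML = TRUE)
  ))
  co <- coef(summary(fit))
  structure(
    list(
      outcome = outcome,
      slope = unname(co["day_index", "Estimate"]),
      slope_se = unname(co["day_index", "Std. Error"]),
      p_value = unname(co["day_index", "Pr(>|t|)"]),
      model_desc = "y ~ day_index + (1 | participant_id), REML",
      n_participants = dplyr::n_distinct(df$participant_id),
      n_days = dplyr::n_distinct(df$day_index),
      fit = fit
    ),
    class = "ema_trend"
  )
}

#' @export
print.ema_trend <- function(x, ...) {
  cat(sprintf(
    "<ema_trend> %s: slope %.3f per day (SE %.3f, p %s); %d participants x %d days\n",
    x$outcome, x$slope, x$slope_se, format.pval(x$p_value, digits = 3),
    x$n_participants, x$n_days))
  invisible(x)
}

#' Compare self-initiated and prompted meal reporting
#'
#' Computes each participant's daily average number of reports per category
#' group (all reports; meals = breakfast + lunch + dinner; each meal; snacks;
#' drinks), using either all study days or only days with at least one report
#' of any type as the denominator, and tests the reporting-mode difference
#' with a linear model adjusted for age and sex.
#'
#' @param reports Meal-report tibble (see [simulate_meal_reports()]); both
#'   modes must be present.
#' @param participants Metadata tibble with `participant_id`, `age`, `sex`.
#'   Participants with missing age or sex are excluded with a warning.
#' @param denominator `"all_days"` (divide by `days`) or `"reporting_days"`
#'   (divide by the participant's number of days with >= 1 report of any
#'   type).
#' @param days Total study days for the `all_days` denominator (default 7).
#' @return Tibble with one row per category group: per-mode median (IQR) of
#'   participant daily averages, the adjusted mode effect `estimate`
#'   (self-initiated minus prompted), its `se` and `p_value`.
#' @export
compare_meal_modes <- function(reports, participants,
                               denominator = c("all_days", "reporting_days"),
                               days = 7L) {
  denominator <- match.arg(denominator)
  reports <- as_tibble(reports)
  participants <- as_tibble(participants)
  if (dplyr::n_distinct(reports$mode) < 2) {
    stop_domain("both reporting modes must be present")
  }
  bad <- is.na(participants$age) | is.na(participants$sex)
  if (any(bad)) {
    warn(sprintf("excluding %d participant(s) with missing age or sex: %s",
                 sum(bad),
                 paste(participants$participant_id[bad], collapse = ", ")))
    participants <- participants[!bad, ]
  }
  reports <- reports[reports$participant_id %in% participants$participant_id, ]

  denom <- reports |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$day_index),
                     .groups = "drop")
  denom$n_days <- if (denominator == "all_days") days else denom$n_days

  cat_groups <- list(
    all = c("breakfast", "lunch", "dinner", "snack", "drink"),
    meals = c("breakfast", "lunch", "dinner"),
    breakfast = "breakfast", lunch = "lunch", dinner = "dinner",
    snacks = "snack", drinks = "drink"
  )
  mode_of <- reports |>
    dplyr::distinct(.data$participant_id, .data$mode)

  purrr::map_dfr(names(cat_groups), function(g) {
    counts <- reports |>
      dplyr::filter(.data$category %in% cat_groups[[g]]) |>
      dplyr::count(.data$participant_id, name = "n_reports")
    per <- mode_of |>
      dplyr::left_join(counts, by = "participant_id") |>
      dplyr::left_join(denom, by = "participant_id") |>
      dplyr::left_join(participants[, c("participant_id", "age", "sex")],
                       by = "participant_id") |>
      dplyr::mutate(
        n_reports = tidyr::replace_na(.data$n_reports, 0L),
        avg = .data$n_reports / .data$n_days,
        mode = factor(.data$mode, levels = c("prompted", "self_initiated"))
      )
    fit <- stats::lm(avg ~ mode + age + sex, data = per)
    co <- coef(summary(fit))
    qs <- function(m) {
      v <- per$avg[per$mode == m]
      if (length(v) == 0) c(NA_real_, NA_real_, NA_real_) else
        unname(quantile_summary(v))
    }
    s <- qs("self_initiated"); p <- qs("prompted")
    tibble(
      category = g,
      self_median = s[1], self_q1 = s[2], self_q3 = s[3],
      prompted_median = p[1], prompted_q1 = p[2], prompted_q3 = p[3],
      estimate = unname(co["modeself_initiated", "Estimate"]),
      se = unname(co["modeself_initiated", "Std. Error"]),
      p_value = unname(co["modeself_initiated", "Pr(>|t|)"])
    )
  })
}

# ---- prompt / meal log CSV schemas -----------------------------------------

#' Write a prompt log CSV
#'
#' Schema: `participant_id,site,day_index,prompt_time,survey_type,
#' scheduled_or_event,bout_end,answered,start_time,completion_seconds`.
#'
#' @param records Prompt-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prompt_csv <- function(records, path) {
  records <- as_tibble(records)
  fmt <- function(t) ifelse(is.na(t), "",
                            format(t, "%Y-%m-%dT%H:%M:%S", tz = .EMASIM_TZ))
  out <- tibble(
    participant_id = records$participant_id,
    site = records$site,
    day_index = records$day_index,
    prompt_time = fmt(records$prompt_time),
    survey_type = records$survey_type,
    scheduled_or_event = ifelse(
      records$survey_type %in% c("sedentary", "walking", "running"),
      "event", "scheduled"),
    bout_end = if ("bout_end" %in% names(records)) fmt(records$bout_end) else "",
    answered = records$answered,
    start_time = fmt(records$prompt_time + records$latency_s),
    completion_seconds = records$completion_s
  )
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a prompt log CSV
#'
#' @param path Path to a prompt log written by [write_prompt_csv()].
#' @return Prompt-record tibble with `latency_s` recomputed from the prompt
#'   and start times.
#' @export
read_prompt_csv <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("participant_id", "site", "day_index", "prompt_time",
              "survey_type", "answered", "start_time", "completion_seconds")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  pt <- as.POSIXct(raw$prompt_time, tz = .EMASIM_TZ,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  st <- as.POSIXct(raw$start_time, tz = .EMASIM_TZ,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  tibble(
    participant_id = raw$participant_id,
    site = raw$site,
    day_index = as.integer(raw$day_index),
    prompt_time = pt,
    survey_type = raw$survey_type,
    answered = as.logical(raw$answered),
    latency_s = as.numeric(st) - as.numeric(pt),
    completion_s = suppressWarnings(as.numeric(raw$completion_seconds))
  )
}

#' Write a meal report CSV
#'
#' Schema: `participant_id,site,day_index,category,mode,report_time`.
#'
#' @param reports Meal-report tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meal_csv <- function(reports, path) {
  reports <- as_tibble(reports)
  out <- reports
  out$report_time <- format(reports$report_time, "%Y-%m-%dT%H:%M:%S",
                            tz = .EMASIM_TZ)
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a meal report CSV
#'
#' @param path Path to a meal report log written by [write_meal_csv()].
#' @return Meal-report tibble.
#' @export
read_meal_csv <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("participant_id", "site", "day_index", "category", "mode",
              "report_time")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  tibble(
    participant_id = raw$participant_id,
    site = raw$site,
    day_index = as.integer(raw$day_index),
    category = raw$category,
    mode = raw$mode,
    report_time = as.POSIXct(raw$report_time, tz = .EMASIM_TZ,
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  )
}
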