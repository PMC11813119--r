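#' Activity profile for the synthetic cohort generator
#'
#' Describes the free-living day structure the generator emulates: a sleep
#' window worn with zero steps, waking time filled by sedentary stretches
#' interleaved with walking bouts, occasional running, and light-activity
#' minutes, plus non-wear gaps. Defaults target the simulation cohort's
#' statistics: mean daily wear time 1,357 (SD 124) minutes and mean daily
#' steps 11,189 (SD 2,881).
#'
#' @param sleep_start,sleep_end Sleep window (`"HH:MM"`, default 23:00–07:00);
#'   worn, zero steps.
#' @param mean_daily_steps,sd_daily_steps Mean/SD of the per-day step target.
#' @param mean_wear_minutes,sd_wear_minutes Target wear statistics
#'   (informational; wear is controlled through the non-wear gap process).
#' @param walk_rate_mean,walk_rate_sd Steps/min of walking minutes (clipped to
#'   the 60–139 walking band).
#' @param walk_bout_mean_min Mean walking-bout duration, minutes.
#' @param run_prob Probability a day contains a running session.
#' @param run_dur_mean_min Mean running-session duration, minutes.
#' @param run_rate_range Steps/min range for running minutes (>= 140).
#' @param light_minutes_mean,light_minutes_sd Daily light-activity minutes
#'   (1–59 steps/min).
#' @param light_chunk_mean_min Mean light-activity chunk duration.
#' @param nonwear_gaps_per_day Expected non-wear gaps per day (Poisson rate);
#'   gaps are carved out of waking sedentary time, emulating device-off
#'   periods such as showers or recharging.
#' @param nonwear_gap_mean_min,nonwear_gap_sd_min Gamma mean/SD of gap length.
#'   Defaults give expected non-wear 1.5 x 55.33 = 83 min/day = 1440 - 1357.
#' @param hr_rate Mean heart-rate samples per worn minute (at least 1 is
#'   always present on worn minutes).
#' @return An object of class `ema_profile`.
#' @export
activity_profile <- function(sleep_start = "23:00", sleep_end = "07:00",
                             mean_daily_steps = 11189, sd_daily_steps = 2881,
                             mean_wear_minutes = 1357, sd_wear_minutes = 124,
                             walk_rate_mean = 95, walk_rate_sd = 8,
                             walk_bout_mean_min = 9,
                             run_prob = 0.25, run_dur_mean_min = 18,
                             run_rate_range = c(140, 165),
                             light_minutes_mean = 170, light_minutes_sd = 40,
                             light_chunk_mean_min = 15,
                             nonwear_gaps_per_day = 1.5,
                             nonwear_gap_mean_min = 55.33,
                             nonwear_gap_sd_min = 30,
                             hr_rate = 12) {
  p <- as.list(environment())
  rates <- c(p$run_prob, p$light_minutes_mean, p$nonwear_gaps_per_day,
             p$mean_daily_steps)
  if (any(rates < 0)) stop_domain("profile rates must be non-negative")
  if (p$walk_bout_mean_min <= 0 || p$light_chunk_mean_min <= 0 ||
      p$nonwear_gap_mean_min <= 0) {
    stop_domain("duration distributions must have positive support")
  }
  structure(p, class = "ema_profile")
}

# gamma draws parameterised by mean and sd
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate one synthetic day of minute epochs
#'
#' Builds a full 1440-minute day: sleep window worn with zero steps; waking
#' time assembled as sedentary filler interleaved with shuffled walking,
#' running, and light-activity segments sized so the day's total step count
#' matches a draw from the profile's step-target distribution; non-wear gaps
#' carved out of sedentary stretches. Uses the session RNG; seed with
#' `set.seed()` (or use [generate_cohort()]).
#'
#' @param profile An [activity_profile()].
#' @param date Civil date of the day.
#' @return A 1440-row tibble of epochs (`minute_start`, `steps`,
#'   `hr_samples`).
#' @export
generate_day <- function(profile, date = as.Date("2023-01-02")) {
  date <- as.Date(date)
  sleep_s <- hm_to_min(profile$sleep_start)
  sleep_e <- hm_to_min(profile$sleep_end)
  mods <- 0:1439
  asleep <- if (sleep_s > sleep_e) (mods >= sleep_s) | (mods < sleep_e) else
    (mods >= sleep_s) & (mods < sleep_e)
  wake_idx <- which(!asleep)  # contiguous block for an overnight sleep window
  n_wake <- length(wake_idx)

  target <- max(0, rnorm(1, profile$mean_daily_steps, profile$sd_daily_steps))

  # running session
  run_steps <- integer(0)
  if (target > 0 && runif(1) < profile$run_prob) {
    dur <- max(6L, as.integer(round(rnorm(1, profile$run_dur_mean_min, 3))))
    run_steps <- as.integer(round(runif(dur, profile$run_rate_range[1],
                                        profile$run_rate_range[2])))
  }
  # light-activity minutes, chunked
  light_total <- max(0L, as.integer(round(rnorm(1, profile$light_minutes_mean,
                                                profile$light_minutes_sd))))
  light_chunks <- list()
  remaining <- light_total
  while (remaining > 0) {
    len <- min(remaining,
               max(1L, as.integer(round(rgamma_ms(1, profile$light_chunk_mean_min,
                                                  profile$light_chunk_mean_min * 0.6)))))
    light_chunks[[length(light_chunks) + 1]] <-
      as.integer(round(runif(len, 1, 59)))
    remaining <- remaining - len
  }
  # walking bouts absorb the residual step budget
  residual <- target - sum(run_steps) -
    sum(unlist(light_chunks) %||% integer(0))
  walk_rate <- min(135, max(65, rnorm(1, profile$walk_rate_mean,
                                      profile$walk_rate_sd)))
  walk_minutes <- max(0L, as.integer(round(residual / walk_rate)))
  walk_bouts <- list()
  remaining <- walk_minutes
  while (remaining > 0) {
    len <- min(remaining,
               max(2L, as.integer(round(rgamma_ms(1, profile$walk_bout_mean_min, 4)))))
    walk_bouts[[length(walk_bouts) + 1]] <-
      as.integer(pmin(139, pmax(60, round(rnorm(len, walk_rate, 6)))))
    remaining <- remaining - len
  }

  segments <- c(
    lapply(walk_bouts, function(s) list(type = "walking", steps = s)),
    lapply(light_chunks, function(s) list(type = "light", steps = s)),
    if (length(run_steps) > 0) list(list(type = "running", steps = run_steps))
  )
  active_total <- sum(vapply(segments, function(s) length(s$steps), integer(1)))
  if (active_total > n_wake) {
    stop_domain(sprintf(
      "infeasible profile: %d active minutes exceed %d waking minutes",
      active_total, n_wake))
  }
  if (length(segments) > 1) segments <- sample(segments)

  # sedentary filler split across the gaps between active segments
  sed_total <- n_wake - active_total
  n_fill <- length(segments) + 1L
  w <- rexp(n_fill)
  fill <- floor(sed_total * w / sum(w))
  fill[1] <- fill[1] + (sed_total - sum(fill))

  steps_wake <- integer(0)
  worn_wake <- logical(0)
  sed_runs <- list()  # (offset into waking time, length) of each filler
  for (i in seq_along(segments)) {
    sed_runs[[i]] <- c(length(steps_wake), fill[i])
    steps_wake <- c(steps_wake, rep(0L, fill[i]), segments[[i]]$steps)
  }
  sed_runs[[n_fill]] <- c(length(steps_wake), fill[n_fill])
  steps_wake <- c(steps_wake, rep(0L, fill[n_fill]))
  worn_wake <- rep(TRUE, n_wake)

  # Non-wear gaps inside sedentary filler (device off: no steps, no HR).
  # A gap longer than its host run spills into further runs so the total
  # non-wear time keeps the gap-process mean (wear calibration depends on it).
  n_gaps <- rpois(1, profile$nonwear_gaps_per_day)
  if (n_gaps > 0) {
    runs <- Filter(function(r) r[2] >= 1, sed_runs)
    lens <- pmax(1L, as.integer(round(rgamma_ms(n_gaps, profile$nonwear_gap_mean_min,
                                                profile$nonwear_gap_sd_min))))
    for (g in lens) {
      while (g > 0 && length(runs) > 0) {
        fits <- which(vapply(runs, `[[`, numeric(1), 2) >= g)
        if (length(fits) > 0) {
          wts <- vapply(runs[fits], `[[`, numeric(1), 2)
          ri <- fits[sample.int(length(fits), 1, prob = wts)]
          r <- runs[[ri]]
          off <- r[1] + sample.int(r[2] - g + 1L, 1) - 1L
          worn_wake[(off + 1):(off + g)] <- FALSE
          runs[[ri]] <- NULL
          left <- c(r[1], off - r[1])
          right <- c(off + g, r[1] + r[2] - (off + g))
          if (left[2] >= 1) runs[[length(runs) + 1]] <- left
          if (right[2] >= 1) runs[[length(runs) + 1]] <- right
          g <- 0L
        } else {
          # consume the longest run entirely and carry the remainder over
          ri <- which.max(vapply(runs, `[[`, numeric(1), 2))
          r <- runs[[ri]]
          worn_wake[(r[1] + 1):(r[1] + r[2])] <- FALSE
          runs[[ri]] <- NULL
          g <- g - r[2]
        }
      }
    }
  }

  steps <- integer(1440)
  worn <- rep(TRUE, 1440)
  steps[wake_idx] <- steps_wake
  worn[wake_idx] <- worn_wake
  hr <- integer(1440)
  hr[worn] <- 1L + rpois(sum(worn), profile$hr_rate)
  tibble(
    minute_start = day_minute(date, mods),
    steps = steps,
    hr_samples = hr
  )
}

#' Generate a synthetic cohort of participant streams
#'
#' Draws per-participant profiles jittered around the cohort means (step
#' target and non-wear propensity), then generates `days` consecutive days per
#' participant. Bit-reproducible under a fixed seed.
#'
#' @param n Number of participants (>= 1).
#' @param profile Cohort-level [activity_profile()].
#' @param days Number of study days per participant (>= 1).
#' @param seed Integer seed.
#' @param start_date First study date.
#' @return Named list of [ema_stream] objects.
#' @export
generate_cohort <- function(n, profile = activity_profile(), days = 7L,
                            seed = 1L, start_date = as.Date("2023-01-02")) {
  if (n < 1) stop_domain("n must be >= 1")
  if (days < 1) stop_domain("days must be >= 1")
  set.seed(seed)
  sites <- rep(c("CZ", "DE", "FR", "IE"), length.out = n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- profile
    # between-participant heterogeneity; within-day variation keeps the rest
    p$mean_daily_steps <- max(0, rnorm(1, profile$mean_daily_steps,
                                       0.6 * profile$sd_daily_steps))
    p$sd_daily_steps <- 0.8 * profile$sd_daily_steps
    p$nonwear_gaps_per_day <- profile$nonwear_gaps_per_day *
      stats::rgamma(1, shape = 10, rate = 10)
    epochs <- purrr::map_dfr(seq_len(days), function(d) {
      generate_day(p, start_date + d - 1)
    })
    out[[i]] <- ema_stream(sprintf("p%02d", i), sites[i], epochs)
  }
  names(out) <- vapply(out, `[[`, character(1), "participant_id")
  out
}

#' Deterministic saturating-day fixtures
#'
#' Fully worn single-day fixtures that maximise bout detection:
#' `sedentary` is 1440 worn zero-step minutes; `walking` is 100 steps/min from
#' 08:00 to 20:00 (zero-step worn elsewhere); `running` is the same at 150
#' steps/min; `mixed` alternates 30-minute zero-step, 12-minute walking, and
#' 12-minute running blocks across 08:00–20:00, each block long enough to
#' qualify under every shipped preset.
#'
#' @param kind One of `"sedentary"`, `"walking"`, `"running"`, `"mixed"`.
#' @param date Civil date of the fixture day.
#' @param site Site label carried by the fixture stream.
#' @return An [ema_stream] covering one day.
#' @export
saturating_day <- function(kind = c("sedentary", "walking", "running", "mixed"),
                           date = as.Date("2023-01-02"), site = "IE") {
  kind <- match.arg(kind)
  mods <- 0:1439
  steps <- integer(1440)
  active <- mods >= 480 & mods < 1200  # 08:00-20:00
  if (kind == "walking") {
    steps[active] <- 100L
  } else if (kind == "running") {
    steps[active] <- 150L
  } else if (kind == "mixed") {
    cycle <- c(rep(0L, 30), rep(100L, 12), rep(150L, 12))
    steps[active] <- rep_len(cycle, sum(active))
  }
  ema_stream(
    paste0("fixture_", kind), site,
    tibble(minute_start = day_minute(date, mods), steps = steps,
           hr_samples = rep(8L, 1440))
  )
}

#' Behavioural model for prompt responses and meal reporting
#'
#' Generative mirror of the compliance analyses: responses follow a linear
#' probability model in study day, latencies a log-normal censored at the
#' survey expiry, completion times a normal (clamped at 10 s) with a daily
#' slope, and meal/snack/drink reports per-category Poisson counts whose
#' total declines linearly over days.
#'
#' @param base_response_rate Response probability on day 1.
#' @param daily_response_slope Change in response probability per day
#'   (default -0.0166, i.e. -1.66 percentage points/day).
#' @param latency_meanlog,latency_sdlog Log-normal parameters of
#'   prompt-to-start latency in seconds (median 120 s by default).
#' @param completion_mean_s Day-1 mean completion time, seconds.
#' @param completion_slope_s Change in completion time per day (default
#'   -1.62 s/day).
#' @param completion_sd_s Completion-time SD, seconds.
#' @param expiry_min Survey expiry bounding answered latencies, minutes.
#' @param meal_rates Named list with elements `self_initiated` and `prompted`,
#'   each a named vector of expected reports/day for `breakfast`, `lunch`,
#'   `dinner`, `snack`, `drink`. Defaults follow the all-days medians of the
#'   two reporting arms.
#' @param meal_daily_slope Change in total expected reports per day
#'   (default -0.17/day), spread across categories in proportion to their
#'   rates.
#' @return An object of class `ema_behaviour`.
#' @export
behaviour_model <- function(base_response_rate = 0.55,
                            daily_response_slope = -0.0166,
                            latency_meanlog = log(120), latency_sdlog = 0.8,
                            completion_mean_s = 72,
                            completion_slope_s = -1.62,
                            completion_sd_s = 20,
                            expiry_min = 8,
                            meal_rates = list(
                              self_initiated = c(breakfast = 0.7, lunch = 0.6,
                                                 dinner = 0.4, snack = 0.6,
                                                 drink = 0.8),
                              prompted = c(breakfast = 0.1, lunch = 0.3,
                                           dinner = 0.1, snack = 0.4,
                                           drink = 0.3)
                            ),
                            meal_daily_slope = -0.17) {
  structure(as.list(environment()), class = "ema_behaviour")
}

#' Simulate prompt responses
#'
#' Marks each prompt answered with probability
#' `clamp(base + slope * (day - 1), 0, 1)`; answered prompts get a latency
#' draw truncated below the expiry and a completion-time draw with the model's
#' daily slope.
#'
#' @param prompts Tibble with columns `participant_id`, `day_index`,
#'   `prompt_time`, and optionally `survey_type` and `site`.
#' @param model A [behaviour_model()].
#' @param seed Optional integer seed.
#' @return A prompt-record tibble: `participant_id`, `site`, `day_index`,
#'   `prompt_time`, `survey_type`, `answered`, `latency_s`, `completion_s`
#'   (`NA` for unanswered prompts).
#' @export
simulate_responses <- function(prompts, model = behaviour_model(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prompts <- as_tibble(prompts)
  n <- nrow(prompts)
  day <- prompts$day_index
  p <- pmin(1, pmax(0, model$base_response_rate +
                      model$daily_response_slope * (day - 1)))
  answered <- runif(n) < p
  expiry_s <- model$expiry_min * 60
  # inverse-CDF draw from the log-normal truncated at the expiry
  u <- runif(n) * plnorm(expiry_s, model$latency_meanlog, model$latency_sdlog)
  latency <- qlnorm(u, model$latency_meanlog, model$latency_sdlog)
  completion <- pmax(10, rnorm(n, model$completion_mean_s +
                                 model$completion_slope_s * (day - 1),
                               model$completion_sd_s))
  tibble(
    participant_id = prompts$participant_id,
    site = col_or(prompts, "site", rep(NA_character_, n)),
    day_index = day,
    prompt_time = prompts$prompt_time,
    survey_type = col_or(prompts, "survey_type", rep("daily", n)),
    answered = answered,
    latency_s = ifelse(answered, latency, NA_real_),
    completion_s = ifelse(answered, completion, NA_real_)
  )
}

col_or <- function(df, col, default) {
  if (col %in% names(df)) df[[col]] else default
}

#' Simulate meal, snack, and drink reports
#'
#' Per participant-day-category counts are Poisson with the mode's category
#' rate, scaled so the expected daily total declines by the model's daily
#' slope.
#'
#' @param participants Tibble of cohort metadata: `participant_id`, and
#'   optionally `site`, `age`, `sex`.
#' @param model A [behaviour_model()].
#' @param mode `"self_initiated"` or `"prompted"`.
#' @param days Number of study days.
#' @param seed Optional integer seed.
#' @param start_date First study date (for report timestamps).
#' @return A meal-report tibble: `participant_id`, `site`, `day_index`,
#'   `category`, `mode`, `report_time`.
#' @export
simulate_meal_reports <- function(participants, model = behaviour_model(),
                                  mode = c("self_initiated", "prompted"),
                                  days = 7L, seed = NULL,
                                  start_date = as.Date("2023-01-02")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  participants <- as_tibble(participants)
  rates <- model$meal_rates[[mode]]
  total <- sum(rates)
  grid <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    day_index = seq_len(days),
    category = names(rates)
  )
  rate_day <- if (total > 0) {
    pmax(0, rates[grid$category] *
           (1 + model$meal_daily_slope * (grid$day_index - 1) / total))
  } else rep(0, nrow(grid))
  counts <- rpois(nrow(grid), rate_day)
  grid <- grid[rep(seq_len(nrow(grid)), counts), ]
  if (nrow(grid) > 0) {
    grid$report_time <- day_minute(start_date + grid$day_index - 1,
                                   sample(420:1379, nrow(grid), replace = TRUE))
  } else {
    grid$report_time <- as.POSIXct(character(), tz = .EMASIM_TZ)
  }
  site_map <- setNames(col_or(participants, "site",
                              rep(NA_character_, nrow(participants))),
                       participants$participant_id)
  tibble(
    participant_id = grid$participant_id,
    site = unname(site_map[grid$participant_id]),
    day_index = grid$day_index,
    category = grid$category,
    mode = mode,
    report_time = grid$report_time
  )
}

#' Synthetic cohort metadata
#'
#' Ages and sexes matching the study population structure (healthy adults,
#' age 31 +- 9, 56% female), for covariate-adjusted comparisons.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param sites Site labels recycled over participants.
#' @return Tibble: `participant_id`, `site`, `age`, `sex`.
#' @export
cohort_metadata <- function(n, seed = 1L,
                            sites = c("CZ", "DE", "FR", "IE")) {
  set.seed(seed)
  tibble(
    participant_id = sprintf("p%02d", seq_len(n)),
    site = rep(sites, length.out = n),
    age = pmin(64, pmax(18, round(rnorm(n, 31, 9)))),
    sex = sample(c("female", "male"), n, replace = TRUE,
                 prob = c(0.56, 0.44))
  )
}
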