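# Fixtures are built in code; no data files.

T0 <- as.POSIXct("2023-01-02 00:00:00", tz = "UTC")
D0 <- as.Date("2023-01-02")

# epochs tibble spanning `n` minutes from `start`
make_epochs <- function(steps, hr = 1L, start = T0) {
  n <- length(steps)
  tibble::tibble(
    minute_start = start + 60 * seq_len(n) - 60,
    steps = as.integer(steps),
    hr_samples = as.integer(rep_len(hr, n))
  )
}

# a random short stream with occasional gaps, exercising all rule branches
random_stream <- function(n = 60, gap_frac = 0.05) {
  steps <- sample(c(rep(0L, 3), sample(0:180, n, replace = TRUE)), n)
  ep <- make_epochs(steps, hr = sample(0:3, n, replace = TRUE,
                                       prob = c(0.15, 0.5, 0.25, 0.1)))
  keep <- sort(sample(n, round(n * (1 - gap_frac))))
  ep[keep, ]
}

# full-day stream with hr present in exactly `worn` minutes
day_with_wear <- function(worn, date = D0) {
  hr <- integer(1440)
  if (worn > 0) hr[sort(sample(1440, worn))] <- 1L
  emasim::ema_stream("w", "CZ", make_epochs(integer(1440), hr = hr,
                                            start = as.POSIXct(paste(date, "00:00:00"), tz = "UTC")))
}

# multi-day stream whose days have the given wear minutes
multi_day_stream <- function(id, wear_by_day, start = D0) {
  ep <- purrr::map_dfr(seq_along(wear_by_day), function(i) {
    hr <- integer(1440)
    w <- wear_by_day[i]
    if (w > 0) hr[seq_len(w)] <- 1L
    make_epochs(integer(1440), hr = hr,
                start = as.POSIXct(paste(start + i - 1, "00:00:00"), tz = "UTC"))
  })
  emasim::ema_stream(id, "DE", ep)
}

# a prompt frame: n_per_day prompts for each participant and day
make_prompts <- function(ids, days = 7, n_per_day = 10) {
  g <- tidyr::expand_grid(participant_id = ids, day_index = seq_len(days),
                          k = seq_len(n_per_day))
  tibble::tibble(
    participant_id = g$participant_id,
    day_index = g$day_index,
    prompt_time = T0 + (g$day_index - 1) * 86400 + 28800 + g$k * 3000,
    survey_type = rep_len(c("morning", "daily", "daily", "daily", "daily",
                            "daily", "evening", "sedentary", "walking",
                            "sedentary")[seq_len(n_per_day)], nrow(g))
  )
}

# the distinct event rules across the shipped presets
preset_rules <- function() {
  rules <- c(emasim::ema_preset("cz_de_original")$rules,
             emasim::ema_preset("ie_fr_relaxed")$rules,
             emasim::ema_preset("optimal")$rules)
  rules[!duplicated(lapply(rules, unclass))]
}
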