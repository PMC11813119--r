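test_that("compliance summaries equal direct computation on constructed logs", {
  rec <- tibble::tibble(
    participant_id = rep(c("a", "b"), each = 10),
    site = "CZ",
    day_index = rep(1:5, 4),
    prompt_time = T0 + seq_len(20) * 3600,
    survey_type = "daily",
    answered = c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 6), rep(FALSE, 4)),
    latency_s = NA_real_,
    completion_s = NA_real_
  )
  rec$latency_s[rec$answered] <- 30
  rec$completion_s[rec$answered] <- 60
  out <- summarise_compliance(rec, days = 5)
  all_row <- out[out$group == "all", ]
  expect_equal(all_row$n_participants, 2)
  expect_equal(all_row$response_rate_median, 0.5)  # participants at 0.4, 0.6
  expect_equal(all_row$latency_s_median, 30)
  expect_equal(all_row$prompts_per_day_median, 2)

  one <- rec[rec$participant_id == "a", ]
  one$answered <- TRUE
  one$latency_s <- 0
  out1 <- summarise_compliance(one, days = 5)
  expect_equal(out1$response_rate_median[out1$group == "all"], 1)
  expect_equal(out1$latency_s_median[out1$group == "all"], 0)
  expect_warning(
    summarise_compliance(one, groups = list(walking = "walking")),
    "no prompts")
})

test_that("response rates stay within [0, 1] and medians within participant extremes", {
  prompts <- make_prompts(sprintf("r%02d", 1:12), days = 7, n_per_day = 8)
  rec <- simulate_responses(prompts, behaviour_model(), seed = 13)
  out <- summarise_compliance(rec)
  per <- tapply(rec$answered, rec$participant_id, mean)
  expect_true(all(out$response_rate_median >= 0 &
                    out$response_rate_median <= 1, na.rm = TRUE))
  all_row <- out[out$group == "all", ]
  expect_gte(all_row$response_rate_median, min(per))
  expect_lte(all_row$response_rate_median, max(per))
})

test_that("daily trends are recovered exactly from noiseless linear outcomes", {
  df <- tidyr::expand_grid(participant_id = sprintf("p%d", 1:6),
                           day_index = 1:7)
  intercepts <- seq(120, 220, length.out = 6)
  df$answered <- TRUE
  df$latency_s <- rep(intercepts, each = 7) - 1 * (df$day_index - 1)
  df$completion_s <- rep(intercepts, each = 7) - 1.62 * (df$day_index - 1)
  expect_equal(fit_daily_trend(df, "latency")$slope, -1, tolerance = 1e-8)
  expect_equal(fit_daily_trend(df, "completion")$slope, -1.62,
               tolerance = 1e-8)
  one_day <- df[df$day_index == 1, ]
  expect_error(fit_daily_trend(one_day, "latency"),
               class = "emasim_domain_error")
  expect_error(fit_daily_trend(df[df$participant_id == "p1", ], "latency"),
               class = "emasim_domain_error")
})

test_that("meal-mode comparison handles denominators, nulls, and real differences", {
  # single participant-day with one breakfast: denominators 1/7 vs 1
  solo <- tibble::tibble(participant_id = "x", site = "CZ", day_index = 1,
                         category = "breakfast", mode = "self_initiated",
                         report_time = T0)
  other <- tibble::tibble(participant_id = "y", site = "FR", day_index = 2,
                          category = "lunch", mode = "prompted",
                          report_time = T0)
  both <- dplyr::bind_rows(solo, other)
  meta <- tibble::tibble(participant_id = c("x", "y"), age = c(30, 40),
                         sex = c("female", "male"))
  all_days <- compare_meal_modes(both, meta, "all_days", days = 7)
  expect_equal(all_days$self_median[all_days$category == "breakfast"], 1 / 7)
  rep_days <- compare_meal_modes(both, meta, "reporting_days")
  expect_equal(rep_days$self_median[rep_days$category == "breakfast"], 1)

  # identical generators -> the adjusted mode effect covers zero
  meta2 <- cohort_metadata(50, seed = 14)
  half <- c(breakfast = 0.5, lunch = 0.5, dinner = 0.5, snack = 0.5,
            drink = 0.5)
  model <- behaviour_model(meal_rates = list(self_initiated = half,
                                             prompted = half),
                           meal_daily_slope = 0)
  a <- simulate_meal_reports(meta2[1:25, ], model, "self_initiated", seed = 15)
  b <- simulate_meal_reports(meta2[26:50, ], model, "prompted", seed = 16)
  null_cmp <- compare_meal_modes(dplyr::bind_rows(a, b), meta2, "all_days")
  all_null <- null_cmp[null_cmp$category == "all", ]
  expect_true(abs(all_null$estimate) < 1.96 * all_null$se)

  # a 1.7 vs 0.7 meals/day difference is detected in the self > prompted direction
  rich <- behaviour_model(meal_daily_slope = 0, meal_rates = list(
    self_initiated = c(breakfast = 0.6, lunch = 0.6, dinner = 0.5,
                       snack = 0.6, drink = 0.8),
    prompted = c(breakfast = 0.2, lunch = 0.3, dinner = 0.2,
                 snack = 0.4, drink = 0.3)))
  a2 <- simulate_meal_reports(meta2[1:25, ], rich, "self_initiated", seed = 17)
  b2 <- simulate_meal_reports(meta2[26:50, ], rich, "prompted", seed = 18)
  cmp <- compare_meal_modes(dplyr::bind_rows(a2, b2), meta2, "all_days")
  meals <- cmp[cmp$category == "meals", ]
  expect_gt(meals$estimate, 0)
  expect_lt(meals$p_value, 0.05)

  # reporting-day averages never fall below all-day averages
  rep_cmp <- compare_meal_modes(dplyr::bind_rows(a2, b2), meta2,
                                "reporting_days")
  expect_true(all(rep_cmp$self_median >= cmp$self_median))

  meta_na <- meta2
  meta_na$age[1] <- NA
  expect_warning(
    compare_meal_modes(dplyr::bind_rows(a2, b2), meta_na, "all_days"),
    "missing age or sex")
  expect_error(compare_meal_modes(a2, meta2), class = "emasim_domain_error")
})

test_that("prompt and meal logs round-trip through their CSV schemas", {
  prompts <- make_prompts(c("p1", "p2"), days = 2, n_per_day = 3)
  prompts$site <- "DE"
  rec <- simulate_responses(prompts, behaviour_model(), seed = 19)
  path <- withr::local_tempfile(fileext = ".csv")
  write_prompt_csv(rec, path)
  back <- read_prompt_csv(path)
  expect_equal(back$answered, rec$answered)
  expect_equal(back$latency_s, round(rec$latency_s),
               tolerance = 1)  # second-resolution timestamps
  expect_equal(back$prompt_time, rec$prompt_time)

  meals <- simulate_meal_reports(cohort_metadata(3, seed = 20),
                                 mode = "prompted", seed = 21)
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_meal_csv(meals, mpath)
  mback <- read_meal_csv(mpath)
  expect_equal(mback$category, meals$category)
  expect_equal(mback$report_time, meals$report_time)

  writeLines("participant_id,site", path)
  expect_error(read_prompt_csv(path), "day_index",
               class = "emasim_format_error")
  expect_error(read_meal_csv(path), "category",
               class = "emasim_format_error")
})
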