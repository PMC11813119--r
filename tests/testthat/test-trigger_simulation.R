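test_that("regular sync schedules have the expected cadence", {
  s15 <- sync_times(sync_model(15, 0), D0)
  expect_length(s15, 96)
  expect_equal(s15[1], as.POSIXct("2023-01-02 00:00:00", tz = "UTC"))
  expect_length(sync_times(sync_model(1440, 0), D0), 1)
  j1 <- sync_times(sync_model(15, 0, "jittered"), D0, seed = 4)
  j2 <- sync_times(sync_model(15, 0, "jittered"), D0, seed = 4)
  expect_equal(j1, j2)
  expect_false(identical(j1, sync_times(sync_model(15, 0, "jittered"), D0,
                                        seed = 5)))
})

test_that("the saturating sedentary day fires 4 capped, spaced triggers", {
  p <- ema_preset("ie_fr_relaxed")
  s <- saturating_day("sedentary")
  b <- find_bouts(s, p$rules$sedentary)
  tr <- simulate_event_triggers(list(sedentary = b), p$sync,
                                p$constraints["sedentary"],
                                dates = s$study_days,
                                total_daily_cap = p$total_daily_cap)
  expect_equal(nrow(tr), 4)
  gaps <- diff(as.numeric(tr$fire_time)) / 60
  expect_true(all(gaps >= 90))
  mod <- (as.numeric(tr$fire_time) %% 86400) / 60
  expect_equal(sum(mod >= 480 & mod < 840), 2)  # 08:00-14:00
  expect_equal(sum(mod >= 840 & mod < 1200), 2) # 14:00-20:00
})

test_that("the saturating walking day fires exactly the daily cap of 3", {
  p <- ema_preset("ie_fr_relaxed")
  w <- saturating_day("walking")
  b <- find_bouts(w, p$rules$walking)
  tr <- simulate_event_triggers(list(walking = b), p$sync,
                                p$constraints["walking"],
                                dates = w$study_days, total_daily_cap = 10)
  expect_equal(nrow(tr), 3)
  expect_true(all(diff(as.numeric(tr$fire_time)) / 60 >= 90))
})

test_that("the backwards span decides whether a bout ending between syncs fires", {
  # one 20-minute sedentary bout whose end-minute is 5 minutes before a sync
  ep <- make_epochs(integer(20), hr = 1L,
                    start = as.POSIXct("2023-01-02 08:36:00", tz = "UTC"))
  rule <- event_rule("sedentary", 20, 0, 0, require_hr_each_minute = TRUE)
  b <- find_bouts(ep, rule)
  expect_equal(max(b$end_minute), as.POSIXct("2023-01-02 08:55:00", tz = "UTC"))
  for (span in c(1, 17)) {
    cst <- schedule_constraints(span, min_interval_min = 90, daily_cap = 4)
    tr <- simulate_event_triggers(list(sedentary = b), sync_model(15, 0),
                                  list(sedentary = cst), dates = D0)
    expect_equal(nrow(tr), if (span == 17) 1 else 0)
    if (nrow(tr) == 1) expect_lte(tr$delay_min, span)
  }
})

test_that("refractory intervals, caps, and spans hold on random bout sets", {
  withr::with_seed(71, {
    for (rep in 1:10) {
      n <- 60
      ends <- sort(T0 + 86400 * sample(0:1, n, TRUE) +
                     60 * sample(0:1439, n, TRUE))
      ends <- ends[!duplicated(ends)]
      b <- tibble::tibble(start_minute = ends - 19 * 60, end_minute = ends,
                          kind = "sedentary", n_outliers = 0L)
      cst <- schedule_constraints(17, min_interval_min = 90, daily_cap = 4,
                                  windows = tibble::tibble(
                                    start = c("08:00", "14:00"),
                                    end = c("14:00", "20:00"), cap = c(2, 2)))
      tr <- simulate_event_triggers(list(sedentary = b), sync_model(15, 0),
                                    list(sedentary = cst),
                                    dates = c(D0, D0 + 1))
      if (nrow(tr) > 1) {
        expect_true(all(diff(as.numeric(tr$fire_time)) / 60 >= 90))
      }
      expect_true(all(tr$delay_min <= 17 & tr$delay_min > 0))
      expect_true(all(!duplicated(tr$bout_end)))
      by_day <- table(as.Date(tr$fire_time))
      expect_true(all(by_day <= 4))
      mod <- (as.numeric(tr$fire_time) %% 86400) / 60
      expect_true(all((mod >= 480 & mod < 840) | (mod >= 840 & mod < 1200)))
    }
  })
})

test_that("relaxing a single constraint never decreases the trigger count", {
  withr::with_seed(72, {
    for (rep in 1:8) {
      ends <- sort(T0 + 60 * sample(0:1439, 40))
      b <- tibble::tibble(start_minute = ends - 9 * 60, end_minute = ends,
                          kind = "walking", n_outliers = 0L)
      base <- schedule_constraints(2, min_interval_min = 90, daily_cap = 3)
      n_base <- nrow(simulate_event_triggers(list(walking = b),
                                             sync_model(15, 0),
                                             list(walking = base), dates = D0))
      relaxed <- list(
        schedule_constraints(17, min_interval_min = 90, daily_cap = 3),
        schedule_constraints(2, min_interval_min = 30, daily_cap = 3),
        schedule_constraints(2, min_interval_min = 90, daily_cap = 10)
      )
      for (cst in relaxed) {
        n_rel <- nrow(simulate_event_triggers(list(walking = b),
                                              sync_model(15, 0),
                                              list(walking = cst), dates = D0))
        expect_gte(n_rel, n_base)
      }
    }
  })
})

test_that("a 17-minute span with regular 15-minute syncs reaches every bout", {
  syncs <- as.numeric(sync_times(sync_model(15, 0), D0))
  withr::with_seed(73, {
    ends <- as.numeric(T0 + 60 * sample(0:1421, 200))
    for (e in ends) {
      in_span <- any(syncs > e & syncs <= e + 17 * 60)
      expect_true(in_span)
    }
  })
})

test_that("time-based scheduling draws 7 in-window prompts per day, 30+ minutes apart", {
  dates <- seq(D0, D0 + 6, by = 1)
  sch <- schedule_time_based(dates, seed = 31)
  expect_equal(nrow(sch), 49)
  expect_true(all(table(sch$date) == 7))
  w <- time_based_windows()
  for (i in seq_len(nrow(sch))) {
    wi <- w[w$label == sch$window[i], ]
    mod <- as.numeric(format(sch$prompt_time[i], "%H")) * 60 +
      as.numeric(format(sch$prompt_time[i], "%M"))
    expect_gte(mod, emasim:::hm_to_min(wi$start))
    expect_lte(mod, emasim:::hm_to_min(wi$end))
  }
  gaps <- diff(sort(as.numeric(sch$prompt_time))) / 60
  expect_true(all(gaps >= 30))
  expect_identical(sch, schedule_time_based(dates, seed = 31))
  expect_false(identical(sch, schedule_time_based(dates, seed = 32)))
})

test_that("the prompt lifecycle issues reminders at 3/6/7 and expires at 8 minutes", {
  lc <- prompt_lifecycle()
  t <- T0 + 10 * 3600
  never <- apply_lifecycle(t, lc, NA)
  expect_false(never$answered)
  expect_equal(never$expired_time, t + 8 * 60)
  expect_equal(never$reminder_times[[1]], t + c(3, 6, 7) * 60)

  instant <- apply_lifecycle(t, lc, 0)
  expect_true(instant$answered)
  expect_equal(instant$n_reminders, 0)

  late <- apply_lifecycle(t, lc, 7.5 * 60)
  expect_true(late$answered)
  expect_equal(late$n_reminders, 3)
  expect_equal(late$start_time, t + 450)

  past_expiry <- apply_lifecycle(t, lc, 8 * 60)
  expect_false(past_expiry$answered)

  expect_error(prompt_lifecycle(c(3, 6, 9), 8), class = "emasim_domain_error")
})
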