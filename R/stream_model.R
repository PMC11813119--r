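#' Construct a participant minute-epoch stream
#'
#' A participant stream holds one wearable's minute-epoch record: per minute,
#' the step count and the number of heart-rate samples logged within the
#' minute. Minutes with no row are "unrecorded" and are distinct from recorded
#' zeros: for wear accounting they behave as `hr_samples = 0`, but the data
#' model keeps them absent so detection rules can distinguish "zero steps
#' while worn" from "no data".
#'
#' @param participant_id Character scalar identifying the participant.
#' @param site Study site, one of `"CZ"`, `"DE"`, `"FR"`, `"IE"`. The site
#'   only selects which trigger preset applied; it carries no time-zone
#'   meaning (all times are local civil time).
#' @param epochs Data frame with columns `minute_start` (POSIXct, aligned to
#'   whole minutes), `steps` and `hr_samples` (non-negative integers). Rows
#'   must be strictly increasing in time; gaps are allowed.
#'
#' @return An object of class `ema_stream`: a list with elements
#'   `participant_id`, `site`, `epochs` (tibble) and `study_days` (the ordered
#'   civil dates covered).
#' @export
#' @examples
#' ep <- tibble::tibble(
#'   minute_start = as.POSIXct("2023-01-02 08:00", tz = "UTC") + 60 * (0:9),
#'   steps = rep(0L, 10), hr_samples = rep(1L, 10)
#' )
#' ema_stream("p01", "CZ", ep)
ema_stream <- function(participant_id, site, epochs) {
  site <- match.arg(site, c("CZ", "DE", "FR", "IE"))
  epochs <- as_tibble(epochs)
  needed <- c("minute_start", "steps", "hr_samples")
  if (!all(needed %in% names(epochs))) {
    stop_format(paste0("epochs must have columns ",
                       paste(needed, collapse = ", ")))
  }
  epochs$minute_start <- as.POSIXct(epochs$minute_start, tz = .EMASIM_TZ)
  if (any(as.numeric(epochs$minute_start) %% 60 != 0)) {
    stop_format("minute_start values must be aligned to whole minutes")
  }
  if (any(epochs$steps < 0) || any(epochs$hr_samples < 0)) {
    stop_domain("steps and hr_samples must be non-negative")
  }
  if (nrow(epochs) > 1 && any(diff(as.numeric(epochs$minute_start)) <= 0)) {
    stop_domain("epochs must be strictly increasing in time with no duplicates")
  }
  epochs$steps <- as.integer(epochs$steps)
  epochs$hr_samples <- as.integer(epochs$hr_samples)
  structure(
    list(
      participant_id = as.character(participant_id),
      site = site,
      epochs = epochs,
      study_days = sort(unique(civil_date(epochs$minute_start)))
    ),
    class = "ema_stream"
  )
}

#' @export
print.ema_stream <- function(x, ...) {
  cat(sprintf(
    "<ema_stream> %s (%s): %d epochs over %d day(s) [%s .. %s]\n",
    x$participant_id, x$site, nrow(x$epochs), length(x$study_days),
    format(min(x$study_days)), format(max(x$study_days))
  ))
  invisible(x)
}

# Expand a stream's epochs onto the complete minute grid between `from` and
# `to` (inclusive minute starts). Unrecorded minutes get steps = 0,
# hr_samples = 0, recorded = FALSE.
minute_grid <- function(epochs, from = NULL, to = NULL) {
  if (nrow(epochs) == 0 && (is.null(from) || is.null(to))) {
    return(tibble(minute_start = as.POSIXct(character(), tz = .EMASIM_TZ),
                  steps = integer(), hr_samples = integer(),
                  recorded = logical()))
  }
  from <- from %||% min(epochs$minute_start)
  to <- to %||% max(epochs$minute_start)
  grid <- seq(from, to, by = 60)
  idx <- match(as.numeric(grid), as.numeric(epochs$minute_start))
  rec <- !is.na(idx)
  tibble(
    minute_start = grid,
    steps = ifelse(rec, epochs$steps[idx], 0L),
    hr_samples = ifelse(rec, epochs$hr_samples[idx], 0L),
    recorded = rec
  )
}

#' Read minute-epoch streams from CSV
#'
#' Reads the minute CSV schema
#' `participant_id,site,timestamp,steps,hr_samples` (UTF-8, header mandatory,
#' ISO-8601 minute-resolution timestamps) and returns one [ema_stream] per
#' distinct participant. Malformed rows are rejected with row-level
#' diagnostics rather than silently dropped.
#'
#' @param path Path to an existing CSV file.
#' @return A named list of [ema_stream] objects (names are participant ids),
#'   sorted by participant id.
#' @export
read_minute_csv <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("participant_id", "site", "timestamp", "steps", "hr_samples")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop_format(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(structure(list(), names = character()))
  }
  row_ids <- seq_len(nrow(raw)) + 1L  # file line numbers (header is line 1)

  bad_int <- function(x) is.na(suppressWarnings(as.numeric(x))) |
    suppressWarnings(as.numeric(x)) %% 1 != 0
  problems <- character()
  for (col in c("steps", "hr_samples")) {
    bad <- bad_int(raw[[col]])
    if (any(bad)) {
      problems <- c(problems, sprintf(
        "non-integer %s at line(s) %s", col,
        paste(head(row_ids[bad], 5), collapse = ", ")))
    }
  }
  ts <- as.POSIXct(raw$timestamp, tz = .EMASIM_TZ,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                                  "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  if (any(is.na(ts))) {
    problems <- c(problems, sprintf(
      "unparseable timestamp at line(s) %s",
      paste(head(row_ids[is.na(ts)], 5), collapse = ", ")))
  }
  key <- paste(raw$participant_id, raw$timestamp)
  dup <- duplicated(key)
  if (any(dup)) {
    first <- row_ids[match(key[dup], key)]
    problems <- c(problems, sprintf(
      "duplicate (participant, minute) at line(s) %s (first seen at line(s) %s)",
      paste(head(row_ids[dup], 5), collapse = ", "),
      paste(head(first, 5), collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop_format(paste(c("malformed minute CSV:", problems), collapse = "\n"))
  }

  df <- tibble(
    participant_id = raw$participant_id,
    site = raw$site,
    minute_start = ts,
    steps = as.integer(raw$steps),
    hr_samples = as.integer(raw$hr_samples)
  )
  split_df <- split(df, df$participant_id)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$minute_start), ]
    ema_stream(d$participant_id[1], d$site[1],
               d[, c("minute_start", "steps", "hr_samples")])
  })
  out[sort(names(out))]
}

#' Write minute-epoch streams to CSV
#'
#' Inverse of [read_minute_csv()]; writes the documented minute CSV schema.
#'
#' @param streams A list of [ema_stream] objects (or a single stream).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(streams, path) {
  if (inherits(streams, "ema_stream")) streams <- list(streams)
  rows <- purrr::map_dfr(streams, function(s) {
    tibble(
      participant_id = s$participant_id,
      site = s$site,
      timestamp = format(s$epochs$minute_start, "%Y-%m-%dT%H:%M:%S",
                         tz = .EMASIM_TZ),
      steps = s$epochs$steps,
      hr_samples = s$epochs$hr_samples
    )
  })
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Wear minutes on a study day
#'
#' A minute counts as worn when at least one heart-rate sample was logged
#' within it (`hr_samples >= 1`); unrecorded minutes count as not worn.
#'
#' @param stream An [ema_stream].
#' @param date A civil date (`Date`) within `stream$study_days`.
#' @return Integer number of worn minutes on `date` (0..1440).
#' @export
wear_minutes <- function(stream, date) {
  date <- as.Date(date)
  if (!date %in% stream$study_days) {
    stop_domain(sprintf("date %s is not in the stream's study days",
                        format(date)))
  }
  ep <- stream$epochs
  on_day <- civil_date(ep$minute_start) == date
  sum(ep$hr_samples[on_day] >= 1L)
}

#' Classify a study day as valid for simulation
#'
#' A valid day has at least `threshold` worn minutes (default 600, i.e. 10
#' hours with at least one heart-rate recording per minute).
#'
#' @inheritParams wear_minutes
#' @param threshold Minimum worn minutes for validity; default 600.
#' @return Logical scalar.
#' @export
is_valid_day <- function(stream, date, threshold = 600L) {
  wear_minutes(stream, date) >= threshold
}

#' Summarise each study day of a stream
#'
#' @inheritParams is_valid_day
#' @return A tibble with one row per study day: `date`, `wear_minutes`,
#'   `total_steps`, `is_valid`.
#' @export
day_summary <- function(stream, threshold = 600L) {
  ep <- stream$epochs
  d <- civil_date(ep$minute_start)
  purrr::map_dfr(stream$study_days, function(day) {
    on <- d == day
    wm <- sum(ep$hr_samples[on] >= 1L)
    tibble(date = day, wear_minutes = wm,
           total_steps = sum(ep$steps[on]),
           is_valid = wm >= threshold)
  })
}

#' Restrict a cohort to participants with enough valid days
#'
#' Keeps the streams with at least `required_days` valid days (default 7, the
#' full study week) and reports the exclusions.
#'
#' @param streams Named list of [ema_stream] objects.
#' @param required_days Minimum number of valid days to retain a participant.
#' @param threshold Valid-day wear threshold in minutes; default 600.
#' @return The retained streams, with an `exclusions` attribute: a tibble of
#'   `participant_id` and `n_valid_days` for every dropped participant. Each
#'   exclusion is also reported as a message.
#' @export
filter_simulation_cohort <- function(streams, required_days = 7L,
                                     threshold = 600L) {
  stopifnot(required_days >= 1)
  n_valid <- vapply(streams, function(s) {
    sum(day_summary(s, threshold)$is_valid)
  }, integer(1))
  keep <- n_valid >= required_days
  excl <- tibble(
    participant_id = unname(vapply(streams[!keep], `[[`, character(1),
                                   "participant_id")),
    n_valid_days = unname(n_valid[!keep])
  )
  if (nrow(excl) > 0) {
    inform(sprintf(
      "excluding %d participant(s) with < %d valid days: %s",
      nrow(excl), required_days,
      paste(sprintf("%s (%d)", excl$participant_id, excl$n_valid_days),
            collapse = ", ")))
  }
  out <- streams[keep]
  attr(out, "exclusions") <- excl
  out
}
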