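# Diary processing: parse raw diary entries, apply exclusion rules with a
# per-reason log, and compute daily self-reported indicators.

#' Read diary entries from CSV
#'
#' TOH diary columns: `participant_id, start, end, worn_flag`. AL diary
#' columns: `participant_id, start, end, place_name, activity_type,
#' indoor_outdoor, stationary, at_home, false_report`. Clock times at
#' minute (or finer) resolution, local civil time.
#'
#' @param path CSV file.
#' @param diary `"toh"` or `"al"`.
#' @return Tibble of entries with POSIXct `start`/`end` and an `entry_id`.
#' @export
read_diary_entries <- function(path, diary = c("toh", "al")) {
  diary <- match.arg(diary)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    start = readr::col_character(),
    end = readr::col_character(),
    .default = readr::col_guess()
  ))
  raw$start <- parse_civil(raw$start)
  raw$end <- parse_civil(raw$end)
  raw$entry_id <- seq_len(nrow(raw))
  tibble::as_tibble(raw)
}

# Split an event interval at midnight so that daily aggregation is
# well-defined; returns one row per civil date touched.
split_at_midnight <- function(events) {
  if (nrow(events) == 0) {
    events$date <- as.Date(character())
    return(events)
  }
  out <- list()
  for (i in seq_len(nrow(events))) {
    s <- events$start[i]; e <- events$end[i]
    mid0 <- as.POSIXct(as.Date(s, tz = "UTC"), tz = "UTC") + 86400
    mids <- if (as.numeric(mid0) < as.numeric(e)) {
      as.numeric(seq(mid0, e, by = 86400))
    } else {
      numeric(0)
    }
    cuts <- civil_time(sort(unique(c(as.numeric(s), mids, as.numeric(e)))))
    cuts <- cuts[as.numeric(cuts) >= as.numeric(s) &
                   as.numeric(cuts) <= as.numeric(e)]
    for (j in seq_len(length(cuts) - 1)) {
      row <- events[i, ]
      row$start <- cuts[j]; row$end <- cuts[j + 1]
      out[[length(out) + 1]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  res$date <- civil_date(res$start)
  res
}

#' Validate reported time-out-of-home diary entries
#'
#' Drops entries outside the study period and entries of duration at most
#' 3 minutes; malformed entries (missing times, end not after start) are
#' also dropped. Every drop is logged with all applicable reasons. Retained
#' entries become self-reported TOH events, split at midnight when they
#' span it.
#'
#' @param entries Tibble from [read_diary_entries()] (`diary = "toh"`).
#' @param study_period Length-2 POSIXct (start, end) of the study.
#' @param min_duration_min Exclusion bound: duration <= this is deleted.
#' @return List: `events` (valid REP TOH events with `date`), `log`
#'   (one row per entry-reason), `n_input`, `n_retained`.
#' @export
validate_toh_entries <- function(entries, study_period,
                                 min_duration_min = 3) {
  res <- validate_entries(entries, study_period, min_duration_min,
                          al_rules = FALSE)
  res$events$kind <- "TOH"
  res$events$source <- "REP"
  res
}

#' Validate reported activity-location diary entries
#'
#' An entry is excluded if any of these holds: outside the study period,
#' missing start/end time, duration at most 3 minutes, non-stationary
#' activity/movement, activity at home, false report. All applicable
#' reasons are logged, so reason tallies can exceed the number of excluded
#' entries.
#'
#' @inheritParams validate_toh_entries
#' @return As [validate_toh_entries()], with AL events.
#' @export
validate_al_entries <- function(entries, study_period,
                                min_duration_min = 3) {
  res <- validate_entries(entries, study_period, min_duration_min,
                          al_rules = TRUE)
  res$events$kind <- "AL"
  res$events$source <- "REP"
  res
}

validate_entries <- function(entries, study_period, min_duration_min,
                             al_rules) {
  n <- nrow(entries)
  reasons <- list()
  add_reason <- function(idx, reason) {
    if (length(idx) > 0) {
      reasons[[length(reasons) + 1]] <<- tibble::tibble(
        entry_id = entries$entry_id[idx], reason = reason)
    }
  }
  missing_time <- is.na(entries$start) | is.na(entries$end)
  add_reason(which(missing_time), "missing start/end time")
  malformed <- !missing_time & entries$end <= entries$start
  add_reason(which(malformed), "malformed (end not after start)")
  usable <- !missing_time & !malformed
  oop <- usable & !(entries$start < study_period[2] &
                      entries$end > study_period[1])
  add_reason(which(oop), "outside study period")
  short <- usable &
    duration_min(entries$start, entries$end) <= min_duration_min
  add_reason(which(short), sprintf("duration <= %g min", min_duration_min))
  excluded <- missing_time | malformed | oop | short
  if (al_rules) {
    nonstat <- usable & !is.na(entries$stationary) & !entries$stationary
    add_reason(which(nonstat), "non-stationary/movement")
    athome <- usable & !is.na(entries$at_home) & entries$at_home
    add_reason(which(athome), "at home")
    false_rep <- usable & !is.na(entries$false_report) & entries$false_report
    add_reason(which(false_rep), "false report")
    excluded <- excluded | nonstat | athome | false_rep
  }
  log <- if (length(reasons)) dplyr::bind_rows(reasons) else
    tibble::tibble(entry_id = integer(), reason = character())
  events <- split_at_midnight(entries[!excluded, , drop = FALSE])
  list(events = events, log = log, n_input = n,
       n_retained = sum(!excluded))
}

#' Aggregate self-reported events to daily indicators
#'
#' Per participant-day: summed reported TOH minutes and counted reported
#' activity locations. Days without entries for a reporting participant are
#' genuine zeros.
#'
#' @param toh_events,al_events Validated REP events (with `date`).
#' @param participants Character vector of participant ids to cover.
#' @param study_dates Vector of civil dates to cover.
#' @return Tibble `participant_id, date, rep_toh_min, rep_nals`.
#' @export
aggregate_daily_rep <- function(toh_events, al_events, participants,
                                study_dates) {
  base <- tidyr::expand_grid(participant_id = participants,
                             date = study_dates)
  toh_sum <- toh_events |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(rep_toh_min = sum(duration_min(.data$start, .data$end)),
                     .groups = "drop")
  al_sum <- al_events |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(rep_nals = dplyr::n(), .groups = "drop")
  base |>
    dplyr::left_join(toh_sum, by = c("participant_id", "date")) |>
    dplyr::left_join(al_sum, by = c("participant_id", "date")) |>
    dplyr::mutate(rep_toh_min = dplyr::coalesce(.data$rep_toh_min, 0),
                  rep_nals = as.integer(dplyr::coalesce(.data$rep_nals, 0L)))
}
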