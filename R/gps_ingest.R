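# GPS ingest: read raw fixes, remove speed outliers, split into
# participant-days, flag day validity by registration period.

#' Read raw GPS fixes
#'
#' Reads a GPS fix stream from CSV (`participant_id,timestamp,lat,lon`,
#' ISO 8601 timestamps) or GPX 1.1 (one file per participant, trackpoints
#' with a `<time>` child). Fixes are sorted chronologically per participant
#' and exact-duplicate timestamps are collapsed to the first occurrence, so
#' timestamps are strictly increasing per participant after ingest.
#'
#' Timestamps are interpreted as local civil clock time (stored as UTC, no
#' DST modelling), matching the clock times used in the diaries.
#'
#' @param path Input file.
#' @param format `"csv"` or `"gpx"`.
#' @param participant_id Participant identifier for GPX input (one track
#'   file per participant). Ignored for CSV.
#' @return A tibble `participant_id, timestamp, lat, lon`.
#' @export
read_fixes <- function(path, format = c("csv", "gpx"),
                       participant_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      participant_id = readr::col_character(),
      timestamp = readr::col_character(),
      lat = readr::col_double(),
      lon = readr::col_double()
    ))
    ts <- parse_civil(raw$timestamp)
    bad <- which(is.na(ts) | is.na(raw$lat) | is.na(raw$lon))
    if (length(bad) > 0) {
      stop(sprintf("malformed GPS row %d in %s", bad[1], path), call. = FALSE)
    }
    fixes <- tibble::tibble(participant_id = raw$participant_id,
                            timestamp = ts, lat = raw$lat, lon = raw$lon)
  } else {
    if (is.null(participant_id)) {
      stop("participant_id is required for GPX input", call. = FALSE)
    }
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    pts <- xml2::xml_find_all(doc, ".//trkpt")
    if (length(pts) == 0) {
      fixes <- tibble::tibble(participant_id = character(),
                              timestamp = civil_time(numeric()),
                              lat = numeric(), lon = numeric())
    } else {
      lat <- as.numeric(xml2::xml_attr(pts, "lat"))
      lon <- as.numeric(xml2::xml_attr(pts, "lon"))
      tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
      ts <- parse_civil(gsub("Z$", "", tim))
      bad <- which(is.na(lat) | is.na(lon) | is.na(ts))
      if (length(bad) > 0) {
        stop(sprintf("malformed GPX trackpoint %d in %s", bad[1], path),
             call. = FALSE)
      }
      fixes <- tibble::tibble(participant_id = participant_id,
                              timestamp = ts, lat = lat, lon = lon)
    }
  }
  out_lat <- which(abs(fixes$lat) > 90)
  if (length(out_lat) > 0) {
    stop(sprintf("row %d: latitude %g out of [-90, 90]", out_lat[1],
                 fixes$lat[out_lat[1]]), call. = FALSE)
  }
  out_lon <- which(abs(fixes$lon) > 180)
  if (length(out_lon) > 0) {
    stop(sprintf("row %d: longitude %g out of [-180, 180]", out_lon[1],
                 fixes$lon[out_lon[1]]), call. = FALSE)
  }
  fixes |>
    dplyr::arrange(.data$participant_id, .data$timestamp) |>
    dplyr::distinct(.data$participant_id, .data$timestamp,
                    .keep_all = TRUE)
}

#' Remove implausible-speed GPS fixes
#'
#' Forward scan per participant: a fix is dropped when the great-circle
#' speed from the last *retained* fix exceeds `vmax_kmh`, so a burst of
#' consecutive jumps is removed entirely. The default 330 km/h is the speed
#' limit of high-speed trains in the study region. Idempotent.
#'
#' @param fixes Tibble from [read_fixes()], sorted per participant.
#' @param vmax_kmh Maximum plausible speed, km/h.
#' @return The filtered fix tibble.
#' @export
remove_speed_outliers <- function(fixes, vmax_kmh = 330) {
  if (nrow(fixes) == 0) return(fixes)
  vmax_ms <- vmax_kmh / 3.6
  fixes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::filter(cpp_speed_filter(.data$lat, .data$lon,
                                   as.numeric(.data$timestamp), vmax_ms)) |>
    dplyr::ungroup()
}

#' Split fixes into participant-days
#'
#' Assigns every fix to exactly one participant-day by its local civil date
#' (half-open day boundary: a fix at exactly midnight belongs to the
#' starting date). Returns one row per participant-day with the day's fixes
#' as a nested tibble and the registration period, i.e. the time between
#' the first and last fix of the day.
#'
#' @param fixes Tibble of fixes.
#' @return A tibble `participant_id, date, fixes (list), n_fixes,
#'   registration_min`.
#' @export
segment_days <- function(fixes) {
  if (nrow(fixes) == 0) {
    return(tibble::tibble(participant_id = character(),
                          date = as.Date(character()), fixes = list(),
                          n_fixes = integer(), registration_min = numeric()))
  }
  fixes |>
    dplyr::mutate(date = civil_date(.data$timestamp)) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    tidyr::nest(.key = "fixes") |>
    dplyr::ungroup() |>
    dplyr::mutate(
      n_fixes = vapply(.data$fixes, nrow, integer(1)),
      registration_min = vapply(
        .data$fixes,
        function(f) duration_min(min(f$timestamp), max(f$timestamp)),
        numeric(1))
    ) |>
    dplyr::arrange(.data$participant_id, .data$date)
}

#' Flag valid registration days and GPS-eligible participants
#'
#' A day is valid when its registration period (first to last fix) reaches
#' `min_registration_hours`; a participant is GPS-eligible when they have at
#' least `min_valid_days` valid days.
#'
#' @param days Output of [segment_days()].
#' @param min_registration_hours Minimum registration period, hours.
#' @param min_valid_days Minimum number of valid days per participant.
#' @return `days` with logical columns `is_valid` and `participant_eligible`.
#' @export
flag_valid_days <- function(days, min_registration_hours = 9,
                            min_valid_days = 2) {
  days |>
    dplyr::mutate(is_valid = .data$registration_min >=
                    min_registration_hours * 60) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(participant_eligible = sum(.data$is_valid) >=
                    min_valid_days) |>
    dplyr::ungroup()
}
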