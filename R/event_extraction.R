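# GPS event extraction: home-buffer geofencing with event-level temporal
# gap interpolation (time-out-of-home events), and time-based stop
# detection with noise merging and home exclusion (activity locations).

#' Threshold set governing event extraction
#'
#' The three thresholds shared by both indicators: `Tmin`, the minimum
#' event duration; `Dmax`, the home-buffer radius and maximum spatial
#' extent of a stop; `Tmax`, the maximum temporal gap bridged by
#' interpolation. Defaults (Tmin = 6 min, Dmax = 125 m, Tmax = 300 min)
#' are the values the stepwise sensitivity analysis typically selects for
#' week-long older-adult cohorts; see [stepwise_optimize()].
#'
#' @param tmin_min Minimum event duration, minutes.
#' @param dmax_m Spatial extent / home-buffer radius, metres.
#' @param tmax_min Maximum interpolated gap, minutes.
#' @return A named list of class `mobagree_thresholds`.
#' @export
threshold_set <- function(tmin_min = 6, dmax_m = 125, tmax_min = 300) {
  if (tmin_min <= 0 || dmax_m <= 0 || tmax_min <= 0) {
    stop("thresholds must be strictly positive", call. = FALSE)
  }
  if (tmin_min >= 24 * 60) stop("Tmin must be below 24 h", call. = FALSE)
  structure(list(tmin_min = tmin_min, dmax_m = dmax_m, tmax_min = tmax_min),
            class = "mobagree_thresholds")
}

#' Label fixes as home or out of home
#'
#' Every fix within `dmax_m` (inclusive) of the home location counts as
#' home, every fix outside as out of home.
#'
#' @param fixes One day of fixes (`timestamp, lat, lon`).
#' @param home One-row data frame with `lat, lon, is_valid`.
#' @param dmax_m Home-buffer radius in metres.
#' @return `fixes` with a character column `state` ("HOME"/"OH").
#' @export
label_fixes <- function(fixes, home, dmax_m) {
  if (!is.null(home$is_valid) && !isTRUE(home$is_valid[1])) {
    stop("refusing to label fixes against an invalid home location",
         call. = FALSE)
  }
  d <- haversine_m(fixes$lat, fixes$lon, home$lat[1], home$lon[1])
  fixes$state <- ifelse(d <= dmax_m, "HOME", "OH")
  fixes
}

#' Build home/out-of-home/gap episodes from labelled fixes
#'
#' Maximal runs of equal state become episodes. An inter-fix gap of up to
#' `tmax_min` minutes flanked by the same state on both sides is absorbed
#' into one episode (event-level temporal interpolation); a longer gap, or
#' one flanked by unequal states, separates episodes and is reported as a
#' GAP counting toward neither state. Episodes span first to last member
#' fix, so the HOME/OH/GAP durations partition the registration period.
#'
#' @param labelled Output of [label_fixes()], sorted by timestamp.
#' @param tmax_min Maximum interpolated gap, minutes.
#' @return Tibble `state, start, end, duration_min` (state includes "GAP").
#' @export
build_episodes <- function(labelled, tmax_min) {
  n <- nrow(labelled)
  if (n == 0) {
    return(tibble::tibble(state = character(), start = civil_time(numeric()),
                          end = civil_time(numeric()),
                          duration_min = numeric()))
  }
  t <- as.numeric(labelled$timestamp)
  s <- labelled$state
  tmax_s <- tmax_min * 60
  newgrp <- c(FALSE, s[-1] != s[-n] | diff(t) > tmax_s)
  i_start <- which(!duplicated(cumsum(newgrp)))
  i_end <- c(i_start[-1] - 1L, n)
  eps <- tibble::tibble(
    state = s[i_start],
    start = civil_time(t[i_start]),
    end = civil_time(t[i_end])
  )
  insert_gaps(eps)
}

# Insert GAP rows wherever consecutive episodes leave unobserved time.
insert_gaps <- function(eps) {
  eps <- eps[order(eps$start), ]
  k <- nrow(eps)
  if (k > 1) {
    gap_start <- eps$end[-k]
    gap_end <- eps$start[-1]
    has_gap <- as.numeric(gap_end) > as.numeric(gap_start)
    if (any(has_gap)) {
      gaps <- tibble::tibble(state = "GAP", start = gap_start[has_gap],
                             end = gap_end[has_gap])
      eps <- dplyr::bind_rows(eps, gaps)
      eps <- eps[order(eps$start), ]
    }
  }
  eps$duration_min <- duration_min(eps$start, eps$end)
  eps
}

#' Extract time-out-of-home events from an episode sequence
#'
#' Out-of-home episodes lasting at least `tmin_min` become TOH events.
#' Shorter out-of-home episodes are relabelled HOME and adjacent HOME
#' episodes re-merged (again bridging gaps up to `tmax_min`). Short HOME
#' episodes inside out-of-home periods are left untouched: the minimum
#' duration is defined for out-of-home time only.
#'
#' @param episodes Output of [build_episodes()].
#' @param tmin_min Minimum TOH event duration, minutes.
#' @param tmax_min Maximum interpolated gap, minutes (used when re-merging
#'   after relabelling).
#' @return Tibble of episodes with state in HOME/OH/GAP; OH rows are the
#'   TOH events, non-overlapping and ordered.
#' @export
extract_toh_events <- function(episodes, tmin_min, tmax_min) {
  eps <- episodes[episodes$state != "GAP", ]
  if (nrow(eps) == 0) return(episodes[0, ])
  dur <- duration_min(eps$start, eps$end)
  eps$state[eps$state == "OH" & dur < tmin_min] <- "HOME"
  tmax_s <- tmax_min * 60
  merged <- eps[1, ]
  for (i in seq_len(nrow(eps))[-1]) {
    last <- nrow(merged)
    gap_s <- as.numeric(eps$start[i]) - as.numeric(merged$end[last])
    if (eps$state[i] == merged$state[last] && gap_s <= tmax_s) {
      merged$end[last] <- max(merged$end[last], eps$end[i])
    } else {
      merged <- dplyr::bind_rows(merged, eps[i, ])
    }
  }
  insert_gaps(merged)
}

#' Detect stops by time-based sequential clustering
#'
#' Sequential scan over one day of fixes: a candidate cluster opens at an
#' anchor fix; a subsequent fix joins while its distance to the anchor is
#' at most `Dmax` and its time gap to the immediately preceding fix is at
#' most `Tmax`. When the candidate can no longer be extended it closes: a
#' STOP if its time span reaches `Tmin`, otherwise the anchor advances by
#' one fix and the unclaimed fixes are released as MOVE. A STOP is
#' represented by the coordinate-wise median of its member fixes and the
#' interval from first to last member timestamp.
#'
#' @param fixes One day of fixes, sorted by timestamp.
#' @param thresholds A [threshold_set()].
#' @return Tibble of episodes: `kind` (STOP/MOVE/GAP), `start`, `end`,
#'   `duration_min`, `lat`, `lon` (median position, STOP only), `n_fixes`,
#'   plus list-columns `fix_lat`, `fix_lon` with the member coordinates.
#' @export
detect_stops <- function(fixes, thresholds) {
  n <- nrow(fixes)
  empty <- tibble::tibble(kind = character(), start = civil_time(numeric()),
                          end = civil_time(numeric()), duration_min = numeric(),
                          lat = numeric(), lon = numeric(),
                          n_fixes = integer(), fix_lat = list(),
                          fix_lon = list())
  if (n == 0) return(empty)
  t <- as.numeric(fixes$timestamp)
  id <- cpp_detect_stops(fixes$lat, fixes$lon, t, thresholds$dmax_m,
                         thresholds$tmin_min * 60, thresholds$tmax_min * 60)
  tmax_s <- thresholds$tmax_min * 60
  # segment index runs: stop blocks by id; non-stop runs split at gaps > Tmax
  blk <- cumsum(c(1L, as.integer(
    id[-1] != id[-n] | (id[-1] == 0L & diff(t) > tmax_s))))
  i_start <- which(!duplicated(blk))
  i_end <- c(i_start[-1] - 1L, n)
  is_stop <- id[i_start] > 0L
  eps <- tibble::tibble(
    kind = ifelse(is_stop, "STOP", "MOVE"),
    start = civil_time(t[i_start]), end = civil_time(t[i_end]),
    lat = NA_real_, lon = NA_real_,
    n_fixes = i_end - i_start + 1L,
    fix_lat = mapply(function(a, b) fixes$lat[a:b], i_start, i_end,
                     SIMPLIFY = FALSE),
    fix_lon = mapply(function(a, b) fixes$lon[a:b], i_start, i_end,
                     SIMPLIFY = FALSE)
  )
  eps$lat[is_stop] <- vapply(which(is_stop),
                             function(k) median(eps$fix_lat[[k]]), numeric(1))
  eps$lon[is_stop] <- vapply(which(is_stop),
                             function(k) median(eps$fix_lon[[k]]), numeric(1))
  # explicit GAP rows for unbridgeable gaps between episodes
  k <- nrow(eps)
  if (k > 1) {
    gap_s <- as.numeric(eps$start[-1]) - as.numeric(eps$end[-k])
    gi <- which(gap_s > tmax_s)
    if (length(gi) > 0) {
      gaps <- tibble::tibble(kind = "GAP", start = eps$end[gi],
                             end = eps$start[gi + 1], lat = NA_real_,
                             lon = NA_real_, n_fixes = 0L,
                             fix_lat = list(numeric(0))[rep(1, length(gi))],
                             fix_lon = list(numeric(0))[rep(1, length(gi))])
      eps <- dplyr::bind_rows(eps, gaps)
      eps <- eps[order(eps$start), ]
    }
  }
  eps$duration_min <- duration_min(eps$start, eps$end)
  eps[, c("kind", "start", "end", "duration_min", "lat", "lon", "n_fixes",
          "fix_lat", "fix_lon")]
}

#' Merge stops interrupted by short noise episodes
#'
#' MOVE episodes shorter than `move_min_min` (default 3 min) are
#' reinterpreted as NOISE (e.g. indoor signal wandering). Two consecutive
#' STOPs separated only by NOISE and/or GAP episodes merge into one when
#' the distance between their median positions is below `Dmax` and the time
#' from the first STOP's end to the second's start is below `Tmax`; the
#' merged STOP recomputes its median over the union of member fixes.
#' Applied left to right until stable.
#'
#' @param episodes Output of [detect_stops()].
#' @param thresholds A [threshold_set()].
#' @param move_min_min Minimum duration of a genuine move, minutes.
#' @return Episode tibble with kinds STOP/MOVE/NOISE/GAP.
#' @export
merge_noise <- function(episodes, thresholds, move_min_min = 3) {
  eps <- episodes
  if (nrow(eps) == 0) return(eps)
  eps$kind[eps$kind == "MOVE" & eps$duration_min < move_min_min] <- "NOISE"
  tmax_s <- thresholds$tmax_min * 60
  repeat {
    stops <- which(eps$kind == "STOP")
    merged_any <- FALSE
    if (length(stops) >= 2) {
      for (si in seq_len(length(stops) - 1)) {
        a <- stops[si]; b <- stops[si + 1]
        between <- if (b - a > 1) seq(a + 1, b - 1) else integer(0)
        if (length(between) > 0 &&
            !all(eps$kind[between] %in% c("NOISE", "GAP"))) next
        gap_s <- as.numeric(eps$start[b]) - as.numeric(eps$end[a])
        if (gap_s >= tmax_s) next
        if (haversine_m(eps$lat[a], eps$lon[a], eps$lat[b], eps$lon[b]) >=
            thresholds$dmax_m) next
        flat <- c(eps$fix_lat[[a]], eps$fix_lat[[b]])
        flon <- c(eps$fix_lon[[a]], eps$fix_lon[[b]])
        eps$end[a] <- eps$end[b]
        eps$lat[a] <- median(flat); eps$lon[a] <- median(flon)
        eps$n_fixes[a] <- eps$n_fixes[a] + eps$n_fixes[b]
        eps$fix_lat[[a]] <- flat; eps$fix_lon[[a]] <- flon
        eps <- eps[-seq(a + 1, b), ]
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  eps$duration_min <- duration_min(eps$start, eps$end)
  eps
}

#' Drop stops at home; the remainder become activity-location events
#'
#' Stops whose median position lies within `dmax_m` (inclusive) of the home
#' location refer to home and are excluded; only out-of-home stops count as
#' activity locations.
#'
#' @param episodes Episode tibble ([merge_noise()] output).
#' @param home One-row data frame with `lat, lon`.
#' @param dmax_m Home-exclusion radius, metres.
#' @return Tibble of AL stop episodes (kind STOP, away from home).
#' @export
exclude_home_stops <- function(episodes, home, dmax_m) {
  stops <- episodes[episodes$kind == "STOP", ]
  if (nrow(stops) == 0) return(stops)
  d <- haversine_m(stops$lat, stops$lon, home$lat[1], home$lon[1])
  stops[d > dmax_m, ]
}

#' Extract GPS events for one participant-day
#'
#' Runs the full per-day chain: home/out-of-home labelling, episode
#' building with gap interpolation, TOH event extraction, stop detection,
#' noise merging and home-stop exclusion.
#'
#' @param fixes One day of fixes.
#' @param home Resolved home (one row, `lat, lon, is_valid`).
#' @param thresholds A [threshold_set()].
#' @param move_min_min Minimum genuine-move duration, minutes.
#' @return List with `toh` and `al` event tibbles and the underlying
#'   `toh_episodes` / `stop_episodes`.
#' @export
extract_day_gps <- function(fixes, home, thresholds, move_min_min = 3) {
  labelled <- label_fixes(fixes, home, thresholds$dmax_m)
  episodes <- build_episodes(labelled, thresholds$tmax_min)
  toh_eps <- extract_toh_events(episodes, thresholds$tmin_min,
                                thresholds$tmax_min)
  stop_eps <- merge_noise(detect_stops(fixes, thresholds), thresholds,
                          move_min_min)
  als <- exclude_home_stops(stop_eps, home, thresholds$dmax_m)
  list(toh = toh_eps[toh_eps$state == "OH", c("start", "end", "duration_min")],
       al = als[, c("start", "end", "duration_min", "lat", "lon", "n_fixes")],
       toh_episodes = toh_eps, stop_episodes = stop_eps)
}

#' Extract GPS events for a cohort
#'
#' Applies [extract_day_gps()] to every valid day of every GPS-eligible
#' participant with a valid home.
#'
#' @param days Flagged day table ([flag_valid_days()]).
#' @param homes Resolved homes ([resolve_homes()]).
#' @param thresholds A [threshold_set()].
#' @param move_min_min Minimum genuine-move duration, minutes.
#' @return List of event tibbles `toh` and `al` (columns `participant_id,
#'   date, kind, source, start, end, duration_min`, plus position columns
#'   for ALs).
#' @export
extract_gps_events <- function(days, homes, thresholds, move_min_min = 3) {
  use <- days$is_valid & days$participant_eligible &
    days$participant_id %in% homes$participant_id[homes$is_valid]
  idx <- which(use)
  toh <- list(); al <- list()
  for (i in idx) {
    pid <- days$participant_id[i]
    home <- homes[homes$participant_id == pid, ]
    res <- extract_day_gps(days$fixes[[i]], home, thresholds, move_min_min)
    if (nrow(res$toh) > 0) {
      toh[[length(toh) + 1]] <- dplyr::bind_cols(
        tibble::tibble(participant_id = pid, date = days$date[i],
                       kind = "TOH", source = "GPS"), res$toh)
    }
    if (nrow(res$al) > 0) {
      al[[length(al) + 1]] <- dplyr::bind_cols(
        tibble::tibble(participant_id = pid, date = days$date[i],
                       kind = "AL", source = "GPS"), res$al)
    }
  }
  list(
    toh = if (length(toh)) dplyr::bind_rows(toh) else empty_events(),
    al = if (length(al)) dplyr::bind_rows(al) else
      dplyr::bind_cols(empty_events(),
                       tibble::tibble(lat = numeric(), lon = numeric(),
                                      n_fixes = integer()))
  )
}

#' Aggregate GPS events to daily indicators
#'
#' Per participant-day: total TOH duration in minutes and the number of
#' activity locations. Valid days without events are genuine zero-mobility
#' days (0 / 0).
#'
#' @param toh_events,al_events Event tibbles from [extract_gps_events()].
#' @param days Flagged day table; one output row per day listed here.
#' @return Tibble `participant_id, date, gps_toh_min, gps_nals, gps_valid`.
#' @export
aggregate_daily_gps <- function(toh_events, al_events, days) {
  base <- days[, c("participant_id", "date")]
  base$gps_valid <- days$is_valid & days$participant_eligible
  toh_sum <- toh_events |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(gps_toh_min = sum(.data$duration_min), .groups = "drop")
  al_sum <- al_events |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(gps_nals = dplyr::n(), .groups = "drop")
  base |>
    dplyr::left_join(toh_sum, by = c("participant_id", "date")) |>
    dplyr::left_join(al_sum, by = c("participant_id", "date")) |>
    dplyr::mutate(gps_toh_min = dplyr::coalesce(.data$gps_toh_min, 0),
                  gps_nals = as.integer(dplyr::coalesce(.data$gps_nals, 0L)))
}
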