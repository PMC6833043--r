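# Shared fixtures and independent oracles, all built in code.

DAY0 <- as.POSIXct("2019-05-06 00:00:00", tz = "UTC")

mk_fixes <- function(t_s, lat, lon, pid = "p1", day = DAY0) {
  tibble::tibble(participant_id = pid, timestamp = day + t_s,
                 lat = lat, lon = lon)
}

# Offset a base point by metres east/north (spherical, R = 6371.0088 km);
# independent of the package's internal frame helper.
pt_offset <- function(lat0, lon0, east_m = 0, north_m = 0) {
  lat0 <- unname(lat0); lon0 <- unname(lon0)
  m_per_deg <- pi / 180 * 6371008.8
  c(lat = lat0 + north_m / m_per_deg,
    lon = lon0 + east_m / (m_per_deg * cos(lat0 * pi / 180)))
}

mk_events <- function(spans_min, pid = "p1", day = DAY0,
                      source = "REP", kind = "TOH") {
  tibble::tibble(
    participant_id = pid, date = as.Date(day, tz = "UTC"),
    kind = kind, source = source,
    start = day + spans_min[, 1] * 60, end = day + spans_min[, 2] * 60,
    duration_min = spans_min[, 2] - spans_min[, 1]
  )
}

# Error-free simulator configuration: every error process switched off
# (individual processes can be switched back on through ...).
sim_config_errorfree <- function(...) {
  args <- utils::modifyList(
    list(gps_noise_sd = 0, indoor_loss_prob = 0, diary_omission_prob = 0,
         diary_shift_sd = 0, diary_time_round = 0, diary_spurious_prob = 0,
         short_day_prob = 0, home_address_error_sd = 0,
         device_off = list(prob = 0, meanlog = log(90), sdlog = 0.4)),
    list(...))
  do.call(sim_config, args)
}

# Thresholds compatible with the error-free generator: Tmin below the
# shortest true event (visits >= 10 min, outings >= 15 min), Dmax above the
# (zero) noise scale and below the 300 m place spacing, Tmax above the
# longest signal gap (there are none).
thresholds_errorfree <- function() {
  threshold_set(tmin_min = 6, dmax_m = 25, tmax_min = 300)
}

cohort_prep <- function(cohort, ...) {
  prepare_cohort_inputs(
    cohort$fixes,
    dplyr::mutate(cohort$toh_diary, entry_id = dplyr::row_number()),
    dplyr::mutate(cohort$al_diary, entry_id = dplyr::row_number()),
    cohort$homes, cohort$study_period, ...)
}

# --- independent oracles ----------------------------------------------------

oracle_dist_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8)
}

# Stay-point oracle: for each anchor enumerate the maximal consistent prefix
# by exhaustive checking, then replay the scan policy (claim on success,
# advance one fix on failure). R + geosphere, independent of the C++ scan.
oracle_stops <- function(lat, lon, t, dmax_m, tmin_s, tmax_s) {
  n <- length(t)
  id <- integer(n)
  nid <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j + 1L <= n &&
           (t[j + 1L] - t[j]) <= tmax_s &&
           oracle_dist_m(lat[i], lon[i], lat[j + 1L], lon[j + 1L]) <= dmax_m) {
      j <- j + 1L
    }
    if ((t[j] - t[i]) >= tmin_s) {
      nid <- nid + 1L
      id[i:j] <- nid
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  id
}

# Random trajectory day for oracle comparison: alternating stationary bouts
# and movement, irregular sampling with occasional long gaps.
random_day <- function(seed, max_fixes = 200) {
  set.seed(seed)
  n <- sample(20:max_fixes, 1)
  gaps <- sample(c(10, 10, 10, 30, 120, 3600, 20000), n - 1, replace = TRUE,
                 prob = c(0.4, 0.2, 0.15, 0.1, 0.1, 0.04, 0.01))
  t <- cumsum(c(0, gaps))
  x <- numeric(n); y <- numeric(n)
  state_move <- FALSE
  for (i in 2:n) {
    if (runif(1) < 0.05) state_move <- !state_move
    step <- if (state_move) rnorm(2, 0, 40) else rnorm(2, 0, 8)
    x[i] <- x[i - 1] + step[1]
    y[i] <- y[i - 1] + step[2]
  }
  m_per_deg <- pi / 180 * 6371008.8
  list(lat = 50.93 + y / m_per_deg,
       lon = 6.95 + x / (m_per_deg * cos(50.93 * pi / 180)),
       t = t)
}

# Second-grid rasterization IoU oracle for half-open event intervals.
oracle_iou <- function(rep_events, gps_events) {
  grid_secs <- function(ev) {
    if (nrow(ev) == 0) return(integer(0))
    s <- round(as.numeric(ev$start)); e <- round(as.numeric(ev$end))
    unique(unlist(mapply(function(a, b) if (b > a) seq(a, b - 1) else
      integer(0), s, e, SIMPLIFY = FALSE)))
  }
  a <- grid_secs(rep_events); b <- grid_secs(gps_events)
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

# Random event set on one day (possibly empty sides).
random_event_set <- function(seed, pid = "p1") {
  set.seed(seed)
  one_side <- function(k) {
    if (k == 0) return(mk_events(matrix(numeric(0), ncol = 2), pid = pid))
    s <- sort(sample(0:1380, k))
    e <- pmin(1440, s + sample(5:240, k, replace = TRUE))
    keep <- e > s
    mk_events(cbind(s[keep], e[keep]), pid = pid)
  }
  list(rep = one_side(sample(0:6, 1)), gps = one_side(sample(0:6, 1)))
}
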