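home <- tibble::tibble(lat = 50.93, lon = 6.95, is_valid = TRUE)

# a point at an exact spherical distance north of home
north_of_home <- function(d_m) pt_offset(home$lat, home$lon, north_m = d_m)

lab <- function(states, t_s = NULL) {
  n <- length(states)
  if (is.null(t_s)) t_s <- seq(0, by = 60, length.out = n)
  p_oh <- north_of_home(200)
  tibble::tibble(timestamp = DAY0 + t_s,
                 lat = ifelse(states == "HOME", home$lat, p_oh["lat"]),
                 lon = ifelse(states == "HOME", home$lon, p_oh["lon"]),
                 state = states)
}

test_that("geofence labelling uses an inclusive Dmax boundary", {
  at_buffer <- north_of_home(125)
  beyond <- north_of_home(126)
  expect_gt(oracle_dist_m(beyond["lat"], beyond["lon"], home$lat, home$lon),
            125)  # haversine oracle
  fx <- tibble::tibble(
    timestamp = DAY0 + c(0, 10, 20),
    lat = c(home$lat, at_buffer["lat"], beyond["lat"]),
    lon = c(home$lon, at_buffer["lon"], beyond["lon"]))
  # a fix at exactly the buffer distance is inside: use the package metric
  # itself to place the boundary, so the equality is exact
  dmax_exact <- haversine_m(at_buffer["lat"], at_buffer["lon"],
                            home$lat, home$lon)
  out <- label_fixes(fx, home, dmax_m = dmax_exact)
  expect_equal(out$state, c("HOME", "HOME", "OH"))
  expect_error(label_fixes(fx, tibble::tibble(lat = 1, lon = 1,
                                              is_valid = FALSE), 125),
               "invalid home")
})

test_that("episodes interpolate same-state gaps up to Tmax only", {
  # HOME run, 4 h gap, HOME run; Tmax = 5 h -> one episode across the gap
  f1 <- lab(rep("HOME", 10))
  f2 <- lab(rep("HOME", 10), t_s = 4 * 3600 + 9 * 60 + seq(0, 540, 60))
  eps <- build_episodes(dplyr::bind_rows(f1, f2), tmax_min = 300)
  expect_equal(eps$state, "HOME")

  # 6 h gap with Tmax = 5 h -> two episodes and a GAP
  f3 <- lab(rep("HOME", 10), t_s = 6 * 3600 + 9 * 60 + seq(0, 540, 60))
  eps2 <- build_episodes(dplyr::bind_rows(f1, f3), tmax_min = 300)
  expect_equal(eps2$state, c("HOME", "GAP", "HOME"))

  # state change across a 30 min gap -> GAP retained
  f4 <- lab(rep("OH", 5), t_s = 9 * 60 + 30 * 60 + seq(0, 240, 60))
  eps3 <- build_episodes(dplyr::bind_rows(f1, f4), tmax_min = 300)
  expect_equal(eps3$state, c("HOME", "GAP", "OH"))
})

test_that("short out-of-home episodes are absorbed into home", {
  # 45 min OH flanked by HOME -> one TOH event of 45 min
  states <- c(rep("HOME", 10), rep("OH", 46), rep("HOME", 10))
  eps <- build_episodes(lab(states), tmax_min = 300)
  toh <- extract_toh_events(eps, tmin_min = 6, tmax_min = 300)
  expect_equal(toh$state[toh$state == "OH"], "OH")
  expect_equal(toh$duration_min[toh$state == "OH"], 45)

  # 5 min OH with Tmin = 6 -> absorbed, single HOME episode
  states2 <- c(rep("HOME", 10), rep("OH", 6), rep("HOME", 10))
  eps2 <- build_episodes(lab(states2), tmax_min = 300)
  toh2 <- extract_toh_events(eps2, tmin_min = 6, tmax_min = 300)
  expect_equal(toh2$state, "HOME")
  expect_equal(nrow(toh2), 1)

  # a day entirely out of home -> one TOH event spanning first to last fix
  eps3 <- build_episodes(lab(rep("OH", 30)), tmax_min = 300)
  toh3 <- extract_toh_events(eps3, tmin_min = 6, tmax_min = 300)
  expect_equal(toh3$state, "OH")
  expect_equal(toh3$duration_min, 29)
})

test_that("per-day HOME + TOH + GAP durations partition the registration period", {
  set.seed(31)
  for (i in 1:10) {
    states <- sample(c("HOME", "OH"), 120, replace = TRUE,
                     prob = c(0.7, 0.3))
    gaps <- sample(c(60, 600, 7200, 30000), 119, replace = TRUE,
                   prob = c(0.85, 0.1, 0.04, 0.01))
    t_s <- cumsum(c(0, gaps))
    eps <- extract_toh_events(build_episodes(lab(states, t_s), 300), 6, 300)
    expect_equal(sum(eps$duration_min), (max(t_s) - min(t_s)) / 60)
  }
})

test_that("stop detection finds a stationary cluster with its median position", {
  set.seed(7)
  jit <- matrix(runif(120, -8, 8), ncol = 2)  # within 20 m of each other
  pts <- t(apply(jit, 1, function(j) pt_offset(50.93, 6.95, j[1], j[2])))
  fx <- mk_fixes(seq(0, by = 10, length.out = 60), pts[, 1], pts[, 2])
  eps <- detect_stops(fx, threshold_set(tmin_min = 6, dmax_m = 125,
                                        tmax_min = 300))
  stops <- eps[eps$kind == "STOP", ]
  expect_equal(nrow(stops), 1)
  expect_equal(stops$lat, median(pts[, 1]))
  expect_equal(stops$lon, median(pts[, 2]))
  expect_equal(stops$n_fixes, 60L)
})

test_that("a steady walk produces no stop; interior gaps are bridged", {
  # 1.4 m/s sampled at 10 s: any candidate spans about 125/1.4 = 89 s < Tmin
  north <- seq(0, by = 14, length.out = 300)
  pts <- t(vapply(north, function(n) pt_offset(50.93, 6.95, 0, n),
                  numeric(2)))
  fx <- mk_fixes(seq(0, by = 10, length.out = 300), pts[, 1], pts[, 2])
  eps <- detect_stops(fx, threshold_set(6, 125, 300))
  expect_equal(sum(eps$kind == "STOP"), 0)

  # stationary fixes with a 4 h interior gap and Tmax = 5 h -> one stop
  t_s <- c(seq(0, 600, 10), 4 * 3600 + 600 + seq(0, 600, 10))
  fx2 <- mk_fixes(t_s, rep(50.93, length(t_s)), rep(6.95, length(t_s)))
  eps2 <- detect_stops(fx2, threshold_set(6, 125, 300))
  expect_equal(sum(eps2$kind == "STOP"), 1)
  expect_equal(eps2$duration_min[eps2$kind == "STOP"],
               (max(t_s) - min(t_s)) / 60)
})

test_that("stop detection equals the exhaustive prefix oracle on random days", {
  th <- threshold_set(tmin_min = 6, dmax_m = 125, tmax_min = 300)
  for (seed in 1:20) {
    day <- random_day(seed)
    fx <- mk_fixes(day$t, day$lat, day$lon)
    got <- detect_stops(fx, th)
    stops <- got[got$kind == "STOP", ]
    oid <- oracle_stops(day$lat, day$lon, day$t, 125, 6 * 60, 300 * 60)
    o_stops <- which(tabulate(oid) > 0)
    expect_equal(nrow(stops), length(o_stops))
    for (k in seq_along(o_stops)) {
      idx <- which(oid == o_stops[k])
      expect_equal(as.numeric(stops$start[k]) - as.numeric(DAY0),
                   day$t[min(idx)])
      expect_equal(as.numeric(stops$end[k]) - as.numeric(DAY0),
                   day$t[max(idx)])
      expect_equal(stops$n_fixes[k], length(idx))
    }
  }
})

mk_stop_episode <- function(start_min, end_min, centre, n = 10) {
  centre <- unname(centre)
  tibble::tibble(kind = "STOP", start = DAY0 + start_min * 60,
                 end = DAY0 + end_min * 60,
                 duration_min = end_min - start_min,
                 lat = centre[1], lon = centre[2], n_fixes = as.integer(n),
                 fix_lat = list(rep(centre[1], n)),
                 fix_lon = list(rep(centre[2], n)))
}

mk_move_episode <- function(start_min, end_min) {
  tibble::tibble(kind = "MOVE", start = DAY0 + start_min * 60,
                 end = DAY0 + end_min * 60,
                 duration_min = end_min - start_min,
                 lat = NA_real_, lon = NA_real_, n_fixes = 2L,
                 fix_lat = list(numeric(2)), fix_lon = list(numeric(2)))
}

test_that("noise merging joins stops split by sub-3-min wander only", {
  th <- threshold_set(6, 125, 300)
  near <- pt_offset(50.93, 6.95, east_m = 50)
  far <- pt_offset(50.93, 6.95, east_m = 300)

  merged <- merge_noise(dplyr::bind_rows(
    mk_stop_episode(0, 10, c(50.93, 6.95)),
    mk_move_episode(10, 12),
    mk_stop_episode(12, 22, near)), th)
  expect_equal(sum(merged$kind == "STOP"), 1)
  expect_equal(merged$duration_min[merged$kind == "STOP"], 22)
  expect_equal(merged$n_fixes[merged$kind == "STOP"], 20L)

  genuine_move <- merge_noise(dplyr::bind_rows(
    mk_stop_episode(0, 10, c(50.93, 6.95)),
    mk_move_episode(10, 14),
    mk_stop_episode(14, 24, near)), th)
  expect_equal(sum(genuine_move$kind == "STOP"), 2)
  expect_equal(sum(genuine_move$kind == "MOVE"), 1)

  too_far <- merge_noise(dplyr::bind_rows(
    mk_stop_episode(0, 10, c(50.93, 6.95)),
    mk_move_episode(10, 12),
    mk_stop_episode(12, 22, far)), th)
  expect_equal(sum(too_far$kind == "STOP"), 2)
  expect_equal(sum(too_far$kind == "NOISE"), 1)
})

test_that("noise merging never increases stop count nor decreases stop time", {
  th <- threshold_set(6, 125, 300)
  for (seed in 21:30) {
    day <- random_day(seed)
    fx <- mk_fixes(day$t, day$lat, day$lon)
    before <- detect_stops(fx, th)
    after <- merge_noise(before, th)
    expect_lte(sum(after$kind == "STOP"), sum(before$kind == "STOP"))
    expect_gte(sum(after$duration_min[after$kind == "STOP"]),
               sum(before$duration_min[before$kind == "STOP"]))
  }
})

test_that("stops at home are excluded from activity locations", {
  th <- threshold_set(6, 125, 300)
  near_home <- pt_offset(home$lat, home$lon, east_m = 60)
  away <- pt_offset(home$lat, home$lon, east_m = 200)
  eps <- dplyr::bind_rows(mk_stop_episode(0, 10, near_home),
                          mk_stop_episode(20, 30, away))
  als <- exclude_home_stops(eps, home, 125)
  expect_equal(nrow(als), 1)
  expect_equal(als$lat, away[["lat"]])
  expect_equal(nrow(exclude_home_stops(eps[0, ], home, 125)), 0)
})

test_that("daily GPS time out of home is non-increasing in the home radius", {
  cfg <- sim_config(n_participants = 1, n_days = 1, gps_interval = 30,
                    seed = 13)
  coh <- simulate_cohort(cfg)
  fx <- coh$fixes
  h <- tibble::tibble(lat = coh$truth$homes$lat[1],
                      lon = coh$truth$homes$lon[1], is_valid = TRUE)
  toh_at <- function(dmax) {
    eps <- extract_toh_events(
      build_episodes(label_fixes(fx, h, dmax), 300), 6, 300)
    sum(eps$duration_min[eps$state == "OH"])
  }
  vals <- vapply(c(25, 50, 100, 125, 200, 300, 500), toh_at, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("daily aggregation sums durations and counts events, zeros included", {
  days <- tibble::tibble(participant_id = "p1",
                         date = as.Date("2019-05-06") + 0:1,
                         fixes = list(NULL, NULL), n_fixes = c(10L, 10L),
                         registration_min = c(600, 600),
                         is_valid = TRUE, participant_eligible = TRUE)
  toh <- mk_events(rbind(c(60, 120), c(200, 230)), kind = "TOH",
                   source = "GPS")
  al <- mk_events(rbind(c(70, 100), c(105, 110), c(210, 220)), kind = "AL",
                  source = "GPS")
  daily <- aggregate_daily_gps(toh, al, days)
  expect_equal(daily$gps_toh_min, c(90, 0))
  expect_equal(daily$gps_nals, c(3L, 0L))
})

test_that("zero-noise synthetic days reproduce true TOH within one sampling interval per boundary", {
  cfg <- sim_config_errorfree(n_participants = 1, n_days = 2,
                              gps_interval = 10, seed = 21)
  coh <- simulate_cohort(cfg)
  h <- tibble::tibble(lat = coh$truth$homes$lat[1],
                      lon = coh$truth$homes$lon[1], is_valid = TRUE)
  days <- flag_valid_days(segment_days(coh$fixes))
  for (i in seq_len(nrow(days))) {
    res <- extract_day_gps(days$fixes[[i]], h, thresholds_errorfree())
    truth <- coh$truth$toh[coh$truth$toh$date == days$date[i], ]
    expect_equal(nrow(res$toh), nrow(truth))
    # boundary tolerance: geofence crossing time plus one sampling interval
    tol_s <- thresholds_errorfree()$dmax_m / cfg$travel_speed +
      cfg$gps_interval
    expect_true(all(abs(as.numeric(res$toh$start) -
                          as.numeric(truth$start)) <= tol_s))
    expect_true(all(abs(as.numeric(res$toh$end) -
                          as.numeric(truth$end)) <= tol_s))
  }
})
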