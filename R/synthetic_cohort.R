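# Synthetic cohort generator: ground-truth mobility schedules, GPS fix
# streams with realistic error processes, and imperfect diaries. Every
# downstream stage of the package is testable against the known truth.

#' Configuration for the synthetic cohort simulator
#'
#' Defines the data-generating conditions for a simulated study week:
#' multi-day schedules of home / out-of-home episodes containing stationary
#' activity visits, GPS sampling with positional noise, indoor signal loss,
#' device-off periods, and diary reporting errors.
#'
#' @param n_participants Number of participants.
#' @param n_days Study days per participant (default 7, a study week).
#' @param study_start Civil date of the first study day.
#' @param home_coords Optional data frame `participant_id, lat, lon` of true
#'   home positions; by default homes are scattered around `area_center`.
#' @param area_center Named vector `c(lat, lon)` around which homes are drawn.
#' @param outings_per_day_mean Poisson mean of out-of-home episodes per day.
#' @param outing_duration `c(meanlog, sdlog)` of the log-normal duration
#'   (minutes) of walk-only outings (outings without any stationary visit).
#' @param als_per_outing_mean Poisson mean of stationary activity visits per
#'   outing.
#' @param al_duration `c(meanlog, sdlog)` of log-normal visit durations
#'   (minutes), truncated to `al_duration_range`.
#' @param al_duration_range Lower/upper truncation of visit durations (min).
#' @param al_dist_range Range (metres) of visit distances from home; visited
#'   places are kept at least 300 m apart from each other and from home.
#' @param travel_speed Speed (m/s) between places (door-to-door average).
#' @param walk_speed Speed (m/s) for walk-only outings.
#' @param gps_interval Seconds between GPS fixes (default 10; 1 reproduces
#'   1-Hz phone logging).
#' @param gps_noise_sd Isotropic Gaussian positional noise, metres (1 sd).
#' @param indoor_noise_factor Multiplier on `gps_noise_sd` while the
#'   participant is at an indoor activity location (indoor signal wander).
#' @param indoor_loss_prob Probability that a fix is dropped while inside a
#'   building (at home or at an indoor visit). Losses arrive in bursts
#'   (`indoor_loss_run` fixes on average) so that signal outages form
#'   contiguous gaps as real receivers produce, while the per-fix marginal
#'   drop probability stays at `indoor_loss_prob`.
#' @param indoor_loss_run Mean length (in fixes) of an indoor loss burst.
#' @param indoor_al_prob Probability that an activity location is indoors.
#' @param device_off List `prob, meanlog, sdlog`: per-day probability of one
#'   device-off window and the log-normal parameters of its length (minutes).
#' @param short_day_prob Probability that the device is only switched on for
#'   a random 4-8 h window (producing an invalid registration day).
#' @param home_address_error_sd Geocoding error (metres, 1 sd) of the
#'   address-based home relative to the true home.
#' @param diary_omission_prob Probability that a true event is unreported.
#' @param diary_time_round Minutes to which reported clock times are rounded
#'   (default 5; 0 disables rounding).
#' @param diary_shift_sd Gaussian start/end reporting error, minutes (1 sd).
#' @param diary_spurious_prob Per-day probability of a spurious non-stationary
#'   diary entry (a reported movement, excluded by diary validation).
#' @param seed Integer seed; equal configurations give identical cohorts.
#'
#' @return A validated list of class `mobagree_sim_config`.
#' @export
sim_config <- function(n_participants = 5,
                       n_days = 7,
                       study_start = as.Date("2019-05-06"),
                       home_coords = NULL,
                       area_center = c(lat = 50.93, lon = 6.95),
                       outings_per_day_mean = 2,
                       outing_duration = c(meanlog = log(60), sdlog = 0.5),
                       als_per_outing_mean = 1.5,
                       al_duration = c(meanlog = log(45), sdlog = 0.5),
                       al_duration_range = c(10, 240),
                       al_dist_range = c(300, 2000),
                       travel_speed = 5,
                       walk_speed = 1.4,
                       gps_interval = 10,
                       gps_noise_sd = 20,
                       indoor_noise_factor = 3,
                       indoor_loss_prob = 0.3,
                       indoor_loss_run = 30,
                       indoor_al_prob = 0.7,
                       device_off = list(prob = 0.3, meanlog = log(90),
                                         sdlog = 0.4),
                       short_day_prob = 0.07,
                       home_address_error_sd = 15,
                       diary_omission_prob = 0.1,
                       diary_time_round = 5,
                       diary_shift_sd = 5,
                       diary_spurious_prob = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  chk_count <- function(x, f) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]) ||
        cfg[[f]] < 0) {
      stop_field("must be a non-negative number", field = f)
    }
  }
  for (f in c("n_participants", "n_days", "outings_per_day_mean",
              "als_per_outing_mean", "gps_noise_sd", "diary_time_round",
              "diary_shift_sd", "home_address_error_sd")) {
    chk_count(cfg[[f]], f)
  }
  for (f in c("indoor_loss_prob", "diary_omission_prob", "short_day_prob",
              "indoor_al_prob", "diary_spurious_prob")) {
    p <- cfg[[f]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop_field("must be a probability in [0, 1]", field = f)
    }
  }
  if (!is.numeric(cfg$gps_interval) || cfg$gps_interval <= 0) {
    stop_field("must be strictly positive", field = "gps_interval")
  }
  if (!is.numeric(cfg$indoor_loss_run) || cfg$indoor_loss_run < 1) {
    stop_field("must be at least 1 fix", field = "indoor_loss_run")
  }
  if (cfg$travel_speed <= 0 || cfg$walk_speed <= 0) {
    stop_field("must be strictly positive", field = "travel_speed")
  }
  if (!is.list(cfg$device_off) ||
      !all(c("prob", "meanlog", "sdlog") %in% names(cfg$device_off)) ||
      cfg$device_off$prob < 0 || cfg$device_off$prob > 1) {
    stop_field("must be list(prob in [0,1], meanlog, sdlog)",
               field = "device_off")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "mobagree_sim_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

activity_types <- function() {
  c("work", "commercial", "social", "personal_care",
    "culture_religion_education", "recreation", "transportation",
    "unassignable")
}

activity_type_probs <- function() {
  c(work = 0.02, commercial = 0.45, social = 0.08, personal_care = 0.07,
    culture_religion_education = 0.09, recreation = 0.14,
    transportation = 0.10, unassignable = 0.05)
}

# Draw k visit positions (local metres) >= 300 m apart from home and from the
# previous visit; distances from home in al_dist_range.
draw_visit_points <- function(k, cfg) {
  pts <- matrix(0, nrow = k, ncol = 2)
  prev <- c(0, 0)
  for (i in seq_len(k)) {
    for (try in 1:20) {
      d <- runif(1, cfg$al_dist_range[1], cfg$al_dist_range[2])
      th <- runif(1, 0, 2 * pi)
      p <- c(d * sin(th), d * cos(th))
      if (sqrt(sum((p - prev)^2)) >= 300) break
    }
    pts[i, ] <- p
    prev <- p
  }
  pts
}

# Build the segment table of one outing starting at `t0` (seconds). Segments
# are (t0, t1, x0, y0, x1, y1, place, indoor, al_id). Returns NULL when the
# outing cannot fit before `latest_end`.
build_outing <- function(t0, latest_end, cfg, al_counter) {
  k <- rpois(1, cfg$als_per_outing_mean)
  if (k == 0) {
    dur <- clamp(rlnorm(1, cfg$outing_duration[1], cfg$outing_duration[2]),
                 15, 180) * 60
    dur <- round(dur)
    if (t0 + dur > latest_end) dur <- round(latest_end - t0)
    if (dur < 15 * 60) return(NULL)
    half <- dur / 2
    th <- runif(1, 0, 2 * pi)
    reach <- cfg$walk_speed * half
    p <- c(reach * sin(th), reach * cos(th))
    seg_t0 <- c(t0, t0 + half)
    seg_t1 <- c(t0 + half, t0 + dur)
    segs <- tibble::tibble(
      t0 = seg_t0, t1 = seg_t1,
      x0 = c(0, p[1]), y0 = c(0, p[2]), x1 = c(p[1], 0), y1 = c(p[2], 0),
      place = "travel", indoor = FALSE, al_id = NA_integer_
    )
    return(list(segments = segs, end = t0 + dur, als = NULL))
  }
  durs <- round(clamp(rlnorm(k, cfg$al_duration[1], cfg$al_duration[2]),
                      cfg$al_duration_range[1], cfg$al_duration_range[2]) * 60)
  pts <- draw_visit_points(k, cfg)
  repeat {
    path <- rbind(c(0, 0), pts[seq_len(k), , drop = FALSE], c(0, 0))
    legs <- sqrt(rowSums(diff(path)^2))
    travel <- round(legs / cfg$travel_speed)
    total <- sum(travel) + sum(durs[seq_len(k)])
    if (t0 + total <= latest_end || k == 0) break
    k <- k - 1
  }
  if (k == 0) return(NULL)
  t <- t0
  segs <- list()
  als <- list()
  for (i in seq_len(k)) {
    segs[[length(segs) + 1]] <- tibble::tibble(
      t0 = t, t1 = t + travel[i],
      x0 = path[i, 1], y0 = path[i, 2], x1 = path[i + 1, 1],
      y1 = path[i + 1, 2], place = "travel", indoor = FALSE,
      al_id = NA_integer_
    )
    t <- t + travel[i]
    indoor <- runif(1) < cfg$indoor_al_prob
    segs[[length(segs) + 1]] <- tibble::tibble(
      t0 = t, t1 = t + durs[i],
      x0 = path[i + 1, 1], y0 = path[i + 1, 2], x1 = path[i + 1, 1],
      y1 = path[i + 1, 2], place = "al", indoor = indoor,
      al_id = al_counter + i
    )
    als[[i]] <- tibble::tibble(
      al_id = al_counter + i, start = t, end = t + durs[i],
      x = path[i + 1, 1], y = path[i + 1, 2], indoor = indoor
    )
    t <- t + durs[i]
  }
  segs[[length(segs) + 1]] <- tibble::tibble(
    t0 = t, t1 = t + travel[k + 1],
    x0 = path[k + 1, 1], y0 = path[k + 1, 2], x1 = 0, y1 = 0,
    place = "travel", indoor = FALSE, al_id = NA_integer_
  )
  list(segments = dplyr::bind_rows(segs), end = t + travel[k + 1],
       als = dplyr::bind_rows(als))
}

# Two-state (Gilbert) loss process: per-fix marginal loss probability p_i,
# bursts of mean length run_len fixes. p_i = 0 forces the kept state.
markov_loss <- function(p, run_len) {
  n <- length(p)
  lost <- logical(n)
  state <- FALSE
  stay <- 1 - 1 / run_len
  u <- runif(n)
  for (i in seq_len(n)) {
    pi <- p[i]
    if (pi <= 0) {
      state <- FALSE
    } else if (pi >= 1) {
      state <- TRUE
    } else if (state) {
      state <- u[i] < stay
    } else {
      state <- u[i] < pi / ((1 - pi) * run_len)
    }
    lost[i] <- state
  }
  lost
}

round_to_min <- function(t_sec, grain_min) {
  if (grain_min <= 0) return(round(t_sec))
  g <- grain_min * 60
  round(t_sec / g) * g
}

#' Simulate a synthetic study cohort
#'
#' Generates, for each participant-day, a ground-truth schedule of home and
#' out-of-home episodes with nested stationary visits; samples a GPS fix
#' stream along the movement path with Gaussian positional noise, indoor
#' signal loss and device-off gaps; and derives two imperfect diaries
#' (time-out-of-home and activity-location) by applying omission, start/end
#' shift and clock-time rounding to the truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `mobagree_cohort` with elements `fixes`,
#'   `toh_diary`, `al_diary`, `homes` (geocoded addresses), `truth`
#'   (unperturbed ground truth: `toh`, `al`, `homes`) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "mobagree_sim_config")) {
    stop_field("config must come from sim_config()", field = "config")
  }
  cfg <- config
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  t_origin <- as.numeric(as.POSIXct(paste(cfg$study_start, "00:00:00"),
                                    tz = "UTC"))
  study_end <- t_origin + cfg$n_days * 86400
  ids <- sprintf("p%03d", seq_len(cfg$n_participants))

  if (is.null(cfg$home_coords)) {
    homes_true <- tibble::tibble(
      participant_id = ids,
      lat = cfg$area_center[["lat"]] + runif(cfg$n_participants, -0.02, 0.02),
      lon = cfg$area_center[["lon"]] + runif(cfg$n_participants, -0.03, 0.03)
    )
  } else {
    homes_true <- tibble::as_tibble(cfg$home_coords)[, c("participant_id",
                                                         "lat", "lon")]
    ids <- homes_true$participant_id
  }
  geo_err <- offset_latlon(homes_true$lat, homes_true$lon,
                           rnorm(nrow(homes_true), 0, cfg$home_address_error_sd),
                           rnorm(nrow(homes_true), 0, cfg$home_address_error_sd))
  homes_addr <- tibble::tibble(participant_id = homes_true$participant_id,
                               lat = geo_err$lat, lon = geo_err$lon)

  fixes <- list(); toh_truth <- list(); al_truth <- list()
  toh_diary <- list(); al_diary <- list()

  for (p in seq_along(ids)) {
    pid <- ids[p]
    h <- homes_true[p, ]
    al_counter <- 0L
    for (d in seq_len(cfg$n_days)) {
      day0 <- t_origin + (d - 1) * 86400
      wake <- day0 + round(clamp(rnorm(1, 7 * 3600, 1800),
                                 5 * 3600, 9.5 * 3600))
      sleep <- day0 + round(clamp(rnorm(1, 22 * 3600, 2700),
                                  20.5 * 3600, 23.75 * 3600))
      n_out <- rpois(1, cfg$outings_per_day_mean)
      starts <- sort(round(runif(n_out, wake + 1800, sleep - 3600)))

      segs <- list(); day_toh <- list(); day_al <- list()
      cur_end <- wake
      for (s0 in starts) {
        if (s0 < cur_end + 1200) next
        out <- build_outing(s0, sleep - 900, cfg, al_counter)
        if (is.null(out)) next
        segs[[length(segs) + 1]] <- out$segments
        day_toh[[length(day_toh) + 1]] <-
          tibble::tibble(start = s0, end = out$end)
        if (!is.null(out$als) && nrow(out$als) > 0) {
          day_al[[length(day_al) + 1]] <- out$als
          al_counter <- al_counter + nrow(out$als)
        }
        cur_end <- out$end
      }
      outing_segs <- dplyr::bind_rows(segs)

      # fill home segments over [wake, sleep]
      occupied <- if (nrow(outing_segs %||% tibble::tibble()) > 0) {
        dplyr::bind_rows(day_toh)
      } else {
        tibble::tibble(start = numeric(), end = numeric())
      }
      bounds <- sort(unique(c(wake, sleep, occupied$start, occupied$end)))
      home_segs <- list()
      for (i in seq_len(length(bounds) - 1)) {
        a <- bounds[i]; b <- bounds[i + 1]
        if (nrow(occupied) == 0 ||
            !any(occupied$start < b & occupied$end > a)) {
          home_segs[[length(home_segs) + 1]] <- tibble::tibble(
            t0 = a, t1 = b, x0 = 0, y0 = 0, x1 = 0, y1 = 0,
            place = "home", indoor = TRUE, al_id = NA_integer_
          )
        }
      }
      day_segs <- dplyr::arrange(
        dplyr::bind_rows(c(home_segs, list(outing_segs))), .data$t0
      )

      # device-on window and off windows
      if (runif(1) < cfg$short_day_prob) {
        on_len <- runif(1, 4, 8) * 3600
        on_start <- round(runif(1, wake, sleep - on_len))
        on_end <- round(on_start + on_len)
      } else {
        on_start <- wake; on_end <- sleep
      }
      offs <- tibble::tibble(start = numeric(), end = numeric())
      if (runif(1) < cfg$device_off$prob) {
        off_len <- rlnorm(1, cfg$device_off$meanlog, cfg$device_off$sdlog) * 60
        off_start <- round(runif(1, on_start, on_end))
        offs <- tibble::tibble(start = off_start,
                               end = min(off_start + round(off_len), on_end))
      }
      dead <- dplyr::bind_rows(
        offs,
        tibble::tibble(start = wake, end = on_start),
        tibble::tibble(start = on_end, end = sleep)
      )
      dead <- dead[dead$end > dead$start, ]

      # sample the fix stream
      tt <- seq(on_start, on_end, by = cfg$gps_interval)
      if (length(tt) > 0) {
        seg_i <- findInterval(tt, day_segs$t0)
        seg_i[seg_i < 1] <- 1
        sg <- day_segs[seg_i, ]
        frac <- ifelse(sg$t1 > sg$t0, (tt - sg$t0) / (sg$t1 - sg$t0), 0)
        frac <- clamp(frac, 0, 1)
        x <- sg$x0 + frac * (sg$x1 - sg$x0)
        y <- sg$y0 + frac * (sg$y1 - sg$y0)
        sdv <- cfg$gps_noise_sd *
          ifelse(sg$place == "al" & sg$indoor, cfg$indoor_noise_factor, 1)
        if (cfg$gps_noise_sd > 0) {
          x <- x + rnorm(length(tt), 0, sdv)
          y <- y + rnorm(length(tt), 0, sdv)
        }
        loss_p <- ifelse(sg$indoor, cfg$indoor_loss_prob, 0)
        keep <- !markov_loss(loss_p, cfg$indoor_loss_run)
        if (nrow(offs) > 0) {
          keep <- keep & !(tt >= offs$start[1] & tt <= offs$end[1])
        }
        ll <- offset_latlon(h$lat, h$lon, x[keep], y[keep])
        fixes[[length(fixes) + 1]] <- tibble::tibble(
          participant_id = pid, timestamp = civil_time(tt[keep]),
          lat = ll$lat, lon = ll$lon
        )
      }

      # truth records
      if (length(day_toh) > 0) {
        th <- dplyr::bind_rows(day_toh)
        toh_truth[[length(toh_truth) + 1]] <- tibble::tibble(
          participant_id = pid, date = civil_date(civil_time(day0)),
          start = civil_time(th$start), end = civil_time(th$end)
        )
        # diaries: omission, shift, rounding
        for (i in seq_len(nrow(th))) {
          if (runif(1) < cfg$diary_omission_prob) next
          s <- th$start[i] + round(rnorm(1, 0, cfg$diary_shift_sd * 60))
          e <- th$end[i] + round(rnorm(1, 0, cfg$diary_shift_sd * 60))
          s <- round_to_min(s, cfg$diary_time_round)
          e <- round_to_min(e, cfg$diary_time_round)
          if (e <= s) e <- s + 60
          worn <- nrow(dead) == 0 ||
            !any(dead$start < th$end[i] & dead$end > th$start[i])
          toh_diary[[length(toh_diary) + 1]] <- tibble::tibble(
            participant_id = pid, start = civil_time(s), end = civil_time(e),
            worn_flag = worn
          )
        }
      }
      if (length(day_al) > 0) {
        al <- dplyr::bind_rows(day_al)
        ll <- offset_latlon(h$lat, h$lon, al$x, al$y)
        atype <- sample(activity_types(), nrow(al), replace = TRUE,
                        prob = activity_type_probs())
        al_truth[[length(al_truth) + 1]] <- tibble::tibble(
          participant_id = pid, date = civil_date(civil_time(day0)),
          start = civil_time(al$start), end = civil_time(al$end),
          lat = ll$lat, lon = ll$lon, activity_type = atype,
          indoor_outdoor = ifelse(al$indoor, "indoor", "outdoor")
        )
        for (i in seq_len(nrow(al))) {
          if (runif(1) < cfg$diary_omission_prob) next
          s <- al$start[i] + round(rnorm(1, 0, cfg$diary_shift_sd * 60))
          e <- al$end[i] + round(rnorm(1, 0, cfg$diary_shift_sd * 60))
          s <- round_to_min(s, cfg$diary_time_round)
          e <- round_to_min(e, cfg$diary_time_round)
          if (e <= s) e <- s + 60
          al_diary[[length(al_diary) + 1]] <- tibble::tibble(
            participant_id = pid, start = civil_time(s), end = civil_time(e),
            place_name = sprintf("place_%s_%03d", pid, al$al_id[i]),
            activity_type = atype[i],
            indoor_outdoor = ifelse(al$indoor[i], "indoor", "outdoor"),
            stationary = TRUE, at_home = FALSE, false_report = FALSE
          )
        }
      }
      # spurious non-stationary entry (a reported movement)
      if (runif(1) < cfg$diary_spurious_prob) {
        s <- round_to_min(round(runif(1, wake, sleep - 1800)),
                          cfg$diary_time_round)
        e <- round_to_min(s + round(runif(1, 5, 30)) * 60,
                          cfg$diary_time_round)
        if (e <= s) e <- s + 300
        al_diary[[length(al_diary) + 1]] <- tibble::tibble(
          participant_id = pid, start = civil_time(s), end = civil_time(e),
          place_name = "walk", activity_type = "transportation",
          indoor_outdoor = "outdoor", stationary = FALSE, at_home = FALSE,
          false_report = FALSE
        )
      }
    }
  }

  empty_diary_toh <- tibble::tibble(
    participant_id = character(), start = civil_time(numeric()),
    end = civil_time(numeric()), worn_flag = logical()
  )
  empty_diary_al <- tibble::tibble(
    participant_id = character(), start = civil_time(numeric()),
    end = civil_time(numeric()), place_name = character(),
    activity_type = character(), indoor_outdoor = character(),
    stationary = logical(), at_home = logical(), false_report = logical()
  )
  empty_truth_toh <- tibble::tibble(
    participant_id = character(), date = as.Date(character()),
    start = civil_time(numeric()), end = civil_time(numeric())
  )
  empty_truth_al <- tibble::tibble(
    participant_id = character(), date = as.Date(character()),
    start = civil_time(numeric()), end = civil_time(numeric()),
    lat = numeric(), lon = numeric(), activity_type = character(),
    indoor_outdoor = character()
  )

  structure(list(
    config = cfg,
    fixes = if (length(fixes)) dplyr::bind_rows(fixes) else
      tibble::tibble(participant_id = character(),
                     timestamp = civil_time(numeric()),
                     lat = numeric(), lon = numeric()),
    toh_diary = if (length(toh_diary)) dplyr::bind_rows(toh_diary) else
      empty_diary_toh,
    al_diary = if (length(al_diary)) dplyr::bind_rows(al_diary) else
      empty_diary_al,
    homes = homes_addr,
    truth = list(
      toh = if (length(toh_truth)) dplyr::bind_rows(toh_truth) else
        empty_truth_toh,
      al = if (length(al_truth)) dplyr::bind_rows(al_truth) else
        empty_truth_al,
      homes = homes_true
    ),
    study_period = c(start = civil_time(t_origin), end = civil_time(study_end))
  ), class = "mobagree_cohort")
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Produces `gps_fixes.csv`, `toh_diary.csv`, `al_diary.csv`, `homes.csv`
#' and `ground_truth.json` under `path`. Files round-trip through
#' [read_cohort()] without loss beyond the documented 1-s timestamp
#' precision.
#'
#' @param cohort A `mobagree_cohort` from [simulate_cohort()].
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mobagree_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  fx <- cohort$fixes
  fx$timestamp <- fmt_civil(fx$timestamp)
  readr::write_csv(fx, file.path(path, "gps_fixes.csv"))
  td <- cohort$toh_diary
  td$start <- fmt_civil(td$start); td$end <- fmt_civil(td$end)
  readr::write_csv(td, file.path(path, "toh_diary.csv"))
  ad <- cohort$al_diary
  ad$start <- fmt_civil(ad$start); ad$end <- fmt_civil(ad$end)
  readr::write_csv(ad, file.path(path, "al_diary.csv"))
  readr::write_csv(cohort$homes, file.path(path, "homes.csv"))
  tr <- cohort$truth
  tr$toh$start <- fmt_civil(tr$toh$start); tr$toh$end <- fmt_civil(tr$toh$end)
  tr$toh$date <- as.character(tr$toh$date)
  tr$al$start <- fmt_civil(tr$al$start); tr$al$end <- fmt_civil(tr$al$end)
  tr$al$date <- as.character(tr$al$date)
  jsonlite::write_json(
    list(toh = tr$toh, al = tr$al, homes = tr$homes,
         study_period = fmt_civil(cohort$study_period)),
    file.path(path, "ground_truth.json"), digits = NA
  )
  invisible(path)
}

#' Read a cohort fixture written by [write_cohort()]
#'
#' @param path Directory containing the fixture files.
#' @return A list with `fixes`, `toh_diary`, `al_diary`, `homes`, `truth`
#'   and `study_period`, in the in-memory types used by the pipeline.
#' @export
read_cohort <- function(path) {
  fixes <- read_fixes(file.path(path, "gps_fixes.csv"), format = "csv")
  toh_diary <- read_diary_entries(file.path(path, "toh_diary.csv"), "toh")
  al_diary <- read_diary_entries(file.path(path, "al_diary.csv"), "al")
  homes <- readr::read_csv(file.path(path, "homes.csv"),
                           col_types = readr::cols(
                             participant_id = readr::col_character(),
                             lat = readr::col_double(),
                             lon = readr::col_double()))
  gt_path <- file.path(path, "ground_truth.json")
  truth <- NULL
  study_period <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    fix_tbl <- function(x) {
      x <- tibble::as_tibble(x)
      if (nrow(x) == 0) return(x)
      x$start <- parse_civil(x$start); x$end <- parse_civil(x$end)
      x$date <- as.Date(x$date)
      x
    }
    truth <- list(toh = fix_tbl(gt$toh), al = fix_tbl(gt$al),
                  homes = tibble::as_tibble(gt$homes))
    study_period <- parse_civil(gt$study_period)
  }
  list(fixes = fixes, toh_diary = toh_diary, al_diary = al_diary,
       homes = homes, truth = truth, study_period = study_period)
}
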