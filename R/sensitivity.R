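# Threshold sensitivity analysis: agreement (F1, IoU) for both indicators
# as a function of each threshold, and the stepwise optimization with
# re-confirmation.

#' Prepare validated cohort inputs for repeated threshold evaluation
#'
#' Runs the threshold-independent stages once (outlier removal, day
#' segmentation and validity, home resolution, diary validation, daily
#' reported indicators) so that event extraction can be re-run cheaply per
#' threshold setting.
#'
#' @param fixes Raw fix tibble.
#' @param toh_entries,al_entries Diary entry tibbles
#'   ([read_diary_entries()]).
#' @param homes Geocoded addresses (`participant_id, lat, lon`).
#' @param study_period Length-2 POSIXct (start, end).
#' @param inclusion An [inclusion_config()].
#' @param vmax_kmh,min_valid_days,home_eps_m,home_min_pts,max_home_distance_m
#'   Ingest and home-detection constants.
#' @param diary_min_duration_min Diary exclusion bound, minutes.
#' @return List used by [agreement_curve()], [stepwise_optimize()] and
#'   [run_pipeline()].
#' @export
prepare_cohort_inputs <- function(fixes, toh_entries, al_entries, homes,
                                  study_period,
                                  inclusion = inclusion_config(),
                                  vmax_kmh = 330, min_valid_days = 2,
                                  home_eps_m = 60, home_min_pts = 3,
                                  max_home_distance_m = 150,
                                  diary_min_duration_min = 3) {
  n_fixes_raw <- nrow(fixes)
  fixes <- remove_speed_outliers(fixes, vmax_kmh)
  days <- flag_valid_days(segment_days(fixes),
                          inclusion$min_registration_hours, min_valid_days)
  homes_res <- resolve_homes(days, homes, eps_m = home_eps_m,
                             min_pts = home_min_pts,
                             max_home_distance_m = max_home_distance_m)
  vt <- validate_toh_entries(toh_entries, study_period,
                             diary_min_duration_min)
  va <- validate_al_entries(al_entries, study_period,
                            diary_min_duration_min)
  study_dates <- seq(civil_date(study_period[1]),
                     civil_date(study_period[2] - 1), by = "day")
  rep_daily <- aggregate_daily_rep(vt$events, va$events,
                                   homes$participant_id, study_dates)
  list(
    days = days, homes = homes_res,
    rep_toh_events = vt$events, rep_al_events = va$events,
    rep_daily = rep_daily, inclusion = inclusion,
    exclusion_log = list(toh = vt$log, al = va$log),
    manifest = list(
      n_fixes_raw = n_fixes_raw,
      n_fixes_filtered = sum(days$n_fixes),
      n_fix_outliers = n_fixes_raw - sum(days$n_fixes),
      n_days = nrow(days),
      n_valid_days = sum(days$is_valid),
      n_participants = length(unique(homes$participant_id)),
      n_gps_eligible = length(unique(
        days$participant_id[days$participant_eligible])),
      n_homes_valid = sum(homes_res$is_valid),
      toh_entries_input = vt$n_input, toh_entries_valid = vt$n_retained,
      al_entries_input = va$n_input, al_entries_valid = va$n_retained
    )
  )
}

#' Evaluate agreement at one threshold setting
#'
#' Re-runs GPS event extraction with the given thresholds, re-applies the
#' inclusion criteria identically, and computes pooled F1 and mean IoU for
#' both indicators.
#'
#' @param prep Output of [prepare_cohort_inputs()].
#' @param thresholds A [threshold_set()].
#' @return Tibble `indicator, f1, iou, n_matched_days`.
#' @export
evaluate_thresholds <- function(prep, thresholds) {
  ev <- extract_gps_events(prep$days, prep$homes, thresholds)
  gps_daily <- aggregate_daily_gps(ev$toh, ev$al, prep$days)
  ok_home <- prep$homes$participant_id[prep$homes$is_valid]
  gps_daily$gps_valid <- gps_daily$gps_valid &
    gps_daily$participant_id %in% ok_home
  matched <- build_matched_days(prep$rep_daily, gps_daily,
                                prep$rep_toh_events, prep$inclusion)
  one <- function(rep_ev, gps_ev, m) {
    re <- restrict_to_days(rep_ev, m)
    ge <- restrict_to_days(gps_ev, m)
    if (nrow(re) == 0 || nrow(ge) == 0) {
      return(tibble::tibble(f1 = NA_real_, iou = NA_real_,
                            n_matched_days = nrow(m)))
    }
    prf <- suppressWarnings(precision_recall_f1(match_events(re, ge)))
    iou <- suppressWarnings(interval_iou(re, ge))
    tibble::tibble(f1 = prf$f1, iou = iou$mean, n_matched_days = nrow(m))
  }
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(indicator = "toh"),
                     one(prep$rep_toh_events, ev$toh, matched$toh)),
    dplyr::bind_cols(tibble::tibble(indicator = "al"),
                     one(prep$rep_al_events, ev$al, matched$al))
  )
}

#' Default grids for the threshold sensitivity analysis
#'
#' Spans the ranges reported across the stop-detection literature
#' (minimum durations of a few to 30 minutes, spatial extents of 25 to
#' 500 m) plus interpolation gaps up to 7 h.
#'
#' @return Named list of numeric grids `Tmax` (min), `Tmin` (min),
#'   `Dmax` (m).
#' @export
default_grids <- function() {
  list(Tmax = c(10, 30, 60, 120, 180, 240, 300, 360, 420),
       Tmin = 2:15,
       Dmax = c(25, 50, 75, 100, 125, 150, 200, 250, 300, 400, 500))
}

threshold_with <- function(th, parameter, value) {
  switch(parameter,
         Tmin = threshold_set(value, th$dmax_m, th$tmax_min),
         Dmax = threshold_set(th$tmin_min, value, th$tmax_min),
         Tmax = threshold_set(th$tmin_min, th$dmax_m, value),
         stop("unknown parameter: ", parameter, call. = FALSE))
}

#' Agreement curve along one threshold grid
#'
#' For each grid value, substitutes the value into the fixed threshold
#' setting, re-runs event extraction and inclusion, and records pooled F1
#' and mean IoU for both indicators (four series).
#'
#' @param prep Output of [prepare_cohort_inputs()].
#' @param parameter One of `"Tmax"`, `"Tmin"`, `"Dmax"`.
#' @param values Strictly increasing positive grid.
#' @param fixed A [threshold_set()] supplying the other two values.
#' @return Long tibble `parameter, value, indicator, metric, score`.
#' @export
agreement_curve <- function(prep, parameter, values, fixed) {
  stopifnot(all(diff(values) > 0), all(values > 0))
  purrr::map_dfr(values, function(v) {
    th <- tryCatch(threshold_with(fixed, parameter, v), error = function(e) NULL)
    if (is.null(th)) {
      warning(sprintf("skipping degenerate %s = %g", parameter, v))
      return(tibble::tibble(parameter = parameter, value = v,
                            indicator = NA_character_, metric = NA_character_,
                            score = NA_real_))
    }
    res <- evaluate_thresholds(prep, th)
    tidyr::pivot_longer(res[, c("indicator", "f1", "iou")],
                        c("f1", "iou"), names_to = "metric",
                        values_to = "score") |>
      dplyr::mutate(parameter = parameter, value = v, .before = 1)
  })
}

#' Stepwise threshold optimization with re-confirmation
#'
#' Starting from the initial setting (Tmin = 3 min, Tmax = 60 min,
#' Dmax = 100 m), optimizes one threshold at a time while holding the other
#' two constant, in the order Tmax, Tmin, Dmax, then re-confirms Tmin and
#' Tmax. At each step the grid value maximizing the objective - by default
#' the unweighted mean of the four agreement series (F1 and IoU for both
#' indicators) - is carried forward; ties go to the smallest value (the
#' most conservative event definition).
#'
#' @param prep Output of [prepare_cohort_inputs()].
#' @param grids Named list of grids as in [default_grids()].
#' @param initial Initial [threshold_set()].
#' @param weights Named weights for the objective, in the order
#'   `toh_f1, toh_iou, al_f1, al_iou`.
#' @return List `thresholds` (final [threshold_set()]), `curves` (one long
#'   tibble per step), `steps` (selection per step),
#'   `changed_on_reconfirm`.
#' @export
stepwise_optimize <- function(prep, grids = default_grids(),
                              initial = threshold_set(tmin_min = 3,
                                                      dmax_m = 100,
                                                      tmax_min = 60),
                              weights = c(toh_f1 = 1, toh_iou = 1,
                                          al_f1 = 1, al_iou = 1)) {
  steps <- c("Tmax", "Tmin", "Dmax", "Tmin", "Tmax")
  current <- initial
  curves <- list()
  picks <- numeric(length(steps))
  for (i in seq_along(steps)) {
    p <- steps[i]
    cur <- agreement_curve(prep, p, grids[[p]], current)
    curves[[i]] <- cur
    obj <- cur |>
      dplyr::mutate(w = weights[paste(.data$indicator, .data$metric,
                                      sep = "_")]) |>
      dplyr::group_by(.data$value) |>
      dplyr::summarise(objective = sum(.data$w * .data$score) / sum(.data$w),
                       .groups = "drop")
    usable <- obj[!is.na(obj$objective), ]
    if (nrow(usable) == 0) {
      warning("objective undefined on the whole grid for ", p,
              "; keeping current value")
      picks[i] <- switch(p, Tmin = current$tmin_min, Dmax = current$dmax_m,
                         Tmax = current$tmax_min)
      next
    }
    best <- min(usable$value[usable$objective ==
                               max(usable$objective)])
    picks[i] <- best
    current <- threshold_with(current, p, best)
  }
  names(curves) <- paste0("step", seq_along(steps), "_", steps)
  list(thresholds = current,
       curves = curves,
       steps = tibble::tibble(step = seq_along(steps), parameter = steps,
                              selected = picks),
       changed_on_reconfirm = picks[4] != picks[2] || picks[5] != picks[1])
}
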