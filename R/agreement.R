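# Agreement between self-reported and GPS-derived indicators: inclusion
# criteria, event-level temporal-overlap matching (precision/recall/F1,
# IoU, cardinalities, duration decomposition) and day-level statistics
# (repeated-measures Bland-Altman, ICC, Spearman / within-person
# correlations).

#' Inclusion criteria configuration
#'
#' @param min_registration_hours Minimum daily GPS registration period.
#' @param min_reporting_days Minimum days with diary entries for a
#'   participant's reports to count.
#' @param min_matched_days Minimum participant-days with both sides valid.
#' @param contradiction_toh_min A reported-AL day is invalidated when no AL
#'   was reported while more than this many TOH minutes were reported.
#' @param toh_tolerance_min,al_tolerance Tolerance bands used by
#'   [daily_difference_stats()].
#' @return A named list of class `mobagree_inclusion`.
#' @export
inclusion_config <- function(min_registration_hours = 9,
                             min_reporting_days = 2,
                             min_matched_days = 2,
                             contradiction_toh_min = 30,
                             toh_tolerance_min = c(10, 20),
                             al_tolerance = c(0, 1)) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[1:4]) <= 0)) {
    stop("inclusion parameters must be positive", call. = FALSE)
  }
  structure(cfg, class = "mobagree_inclusion")
}

#' Form the matched valid participant-days for both indicators
#'
#' Applies the inclusion rules: a GPS day is invalid when its registration
#' period is too short or the device was reported unworn for at least one
#' reported out-of-home event of that day; reported days of participants
#' with fewer than `min_reporting_days` reporting days are invalid for that
#' indicator; contradictory reported days (no TOH but at least one AL; no
#' AL but more than 30 reported TOH minutes) are invalid; and only
#' participants with at least `min_matched_days` days with both sides
#' valid are compared.
#'
#' @param rep_daily Daily reported indicators ([aggregate_daily_rep()]).
#' @param gps_daily Daily GPS indicators ([aggregate_daily_gps()]).
#' @param rep_toh_events Validated REP TOH events carrying `worn_flag`.
#' @param inclusion An [inclusion_config()].
#' @return List with matched-day tibbles `toh` and `al` (`participant_id,
#'   date, rep, gps, diff`) and a `summary` of exclusion tallies.
#' @export
build_matched_days <- function(rep_daily, gps_daily, rep_toh_events,
                               inclusion = inclusion_config()) {
  daily <- dplyr::inner_join(rep_daily, gps_daily,
                             by = c("participant_id", "date"))
  unworn <- rep_toh_events |>
    dplyr::filter(!is.na(.data$worn_flag), !.data$worn_flag) |>
    dplyr::distinct(.data$participant_id, .data$date) |>
    dplyr::mutate(unworn = TRUE)
  daily <- daily |>
    dplyr::left_join(unworn, by = c("participant_id", "date")) |>
    dplyr::mutate(gps_ok = .data$gps_valid & is.na(.data$unworn))

  # reporting-day counts per indicator
  rep_days <- daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      toh_rep_days = dplyr::n_distinct(.data$date[.data$rep_toh_min > 0]),
      al_rep_days = dplyr::n_distinct(.data$date[.data$rep_nals > 0]),
      .groups = "drop")
  daily <- dplyr::left_join(daily, rep_days, by = "participant_id")

  daily <- daily |>
    dplyr::mutate(
      rep_toh_ok = .data$toh_rep_days >= inclusion$min_reporting_days &
        !(.data$rep_toh_min == 0 & .data$rep_nals >= 1),
      rep_al_ok = .data$al_rep_days >= inclusion$min_reporting_days &
        !(.data$rep_nals == 0 &
            .data$rep_toh_min > inclusion$contradiction_toh_min)
    )

  pick <- function(rep_col, ok_col, gps_col) {
    m <- daily |>
      dplyr::filter(.data[[ok_col]], .data$gps_ok) |>
      dplyr::transmute(.data$participant_id, .data$date,
                       rep = .data[[rep_col]], gps = .data[[gps_col]]) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::filter(dplyr::n() >= inclusion$min_matched_days) |>
      dplyr::ungroup() |>
      dplyr::mutate(diff = .data$rep - .data$gps)
    m
  }
  toh <- pick("rep_toh_min", "rep_toh_ok", "gps_toh_min")
  al <- pick("rep_nals", "rep_al_ok", "gps_nals")
  list(
    toh = toh, al = al,
    summary = list(
      n_days = nrow(daily),
      n_gps_valid_days = sum(daily$gps_ok),
      n_unworn_days = sum(!is.na(daily$unworn)),
      n_matched_toh_days = nrow(toh),
      n_matched_al_days = nrow(al),
      n_participants_toh = dplyr::n_distinct(toh$participant_id),
      n_participants_al = dplyr::n_distinct(al$participant_id)
    )
  )
}

restrict_to_days <- function(events, matched) {
  dplyr::semi_join(events, matched, by = c("participant_id", "date"))
}

#' Match events by temporal overlap
#'
#' Two events from opposite sources match when their intersection duration
#' is strictly positive (abutting events do not match). Each event is
#' annotated with its number of matches, its match cardinality (1:0, 1:1,
#' 1:n) and its overlap fraction (overlapped duration over own duration).
#'
#' @param rep_events,gps_events Event tibbles (same participant set,
#'   matched valid days).
#' @return List of annotated tibbles `rep` and `gps`.
#' @export
match_events <- function(rep_events, gps_events) {
  annotate <- function(a, b) {
    if (nrow(a) == 0) {
      a$n_matches <- integer(0); a$cardinality <- character(0)
      a$overlap_fraction <- numeric(0)
      return(a)
    }
    a$n_matches <- 0L
    a$overlap_fraction <- 0
    for (pid in unique(a$participant_id)) {
      ai <- which(a$participant_id == pid)
      bi <- which(b$participant_id == pid)
      ra <- iv_ranges(a$start[ai], a$end[ai])
      if (length(ra) != length(ai)) {
        stop("events with non-positive duration cannot be matched",
             call. = FALSE)
      }
      if (length(bi) == 0) next
      rb <- iv_ranges(b$start[bi], b$end[bi])
      hits <- IRanges::findOverlaps(ra, rb)
      a$n_matches[ai] <- tabulate(S4Vectors::queryHits(hits), length(ra))
      rb_merged <- IRanges::reduce(rb)
      h2 <- IRanges::findOverlaps(ra, rb_merged)
      ov <- numeric(length(ra))
      if (length(h2) > 0) {
        w <- as.numeric(IRanges::width(IRanges::pintersect(
          ra[S4Vectors::queryHits(h2)], rb_merged[S4Vectors::subjectHits(h2)])))
        agg <- rowsum(w, S4Vectors::queryHits(h2))
        ov[as.integer(rownames(agg))] <- agg[, 1]
      }
      a$overlap_fraction[ai] <- ov / as.numeric(IRanges::width(ra))
    }
    a$cardinality <- dplyr::case_when(
      a$n_matches == 0L ~ "1:0",
      a$n_matches == 1L ~ "1:1",
      TRUE ~ "1:n")
    a
  }
  list(rep = annotate(rep_events, gps_events),
       gps = annotate(gps_events, rep_events))
}

#' Match-cardinality summary table
#'
#' Counts and integer percentages of events with exactly one (1:1),
#' multiple (1:n) and no (1:0) temporally overlapping counterpart, plus
#' the at-least-one-match rate.
#'
#' @param records Annotated event tibble from [match_events()].
#' @return Tibble `cardinality, n, pct` with an attached attribute
#'   `match_rate` (share of events with n_matches >= 1).
#' @export
summarize_match_cardinality <- function(records) {
  total <- nrow(records)
  out <- tibble::tibble(cardinality = c("1:1", "1:n", "1:0"))
  out$n <- unname(vapply(out$cardinality,
                         function(k) sum(records$cardinality == k),
                         numeric(1)))
  out$pct <- round(100 * out$n / total)
  attr(out, "match_rate") <- sum(records$n_matches >= 1) / total
  attr(out, "total") <- total
  out
}

#' Pooled precision, recall and F1 of event matching
#'
#' Recall: matched reported events over all reported events. Precision:
#' matched GPS events over all GPS events. F1 is their harmonic mean.
#' Pooled over all events of all participants. A zero denominator yields a
#' missing metric with a warning.
#'
#' @param matches Output of [match_events()].
#' @return List `precision, recall, f1, n_rep, n_gps`.
#' @export
precision_recall_f1 <- function(matches) {
  n_rep <- nrow(matches$rep); n_gps <- nrow(matches$gps)
  recall <- if (n_rep == 0) {
    warning("no reported events: recall undefined"); NA_real_
  } else sum(matches$rep$n_matches >= 1) / n_rep
  precision <- if (n_gps == 0) {
    warning("no GPS events: precision undefined"); NA_real_
  } else sum(matches$gps$n_matches >= 1) / n_gps
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_rep = n_rep, n_gps = n_gps)
}

#' Interval intersection-over-union per participant
#'
#' IoU of the merged reported and GPS event timelines, computed per
#' participant over all events of all matched days, then averaged over
#' participants. Participants with zero total event time are excluded from
#' the mean with a warning.
#'
#' @param rep_events,gps_events Event tibbles on matched valid days.
#' @return List `per_participant` (tibble `participant_id, iou`) and
#'   `mean`.
#' @export
interval_iou <- function(rep_events, gps_events) {
  ids <- sort(unique(c(rep_events$participant_id, gps_events$participant_id)))
  per <- purrr::map_dfr(ids, function(pid) {
    ra <- events_ranges(rep_events[rep_events$participant_id == pid, ])
    rb <- events_ranges(gps_events[gps_events$participant_id == pid, ])
    uni <- iv_seconds(IRanges::reduce(c(ra, rb)))
    if (uni == 0) {
      return(tibble::tibble(participant_id = pid, iou = NA_real_))
    }
    tibble::tibble(participant_id = pid,
                   iou = iv_intersect_seconds(ra, rb) / uni)
  })
  if (any(is.na(per$iou))) {
    warning("participants with zero event time excluded from IoU mean")
  }
  list(per_participant = per, mean = mean(per$iou, na.rm = TRUE))
}

#' Duration decomposition of the union timeline
#'
#' Splits the union of reported and GPS event time into intersection,
#' reported-only and GPS-only fractions, per participant, then averages
#' the three percentages over participants (they sum to 100 per
#' participant).
#'
#' @param rep_events,gps_events Event tibbles on matched valid days.
#' @return List `per_participant` and `mean` (named vector of the three
#'   percentages).
#' @export
duration_decomposition <- function(rep_events, gps_events) {
  ids <- sort(unique(c(rep_events$participant_id, gps_events$participant_id)))
  per <- purrr::map_dfr(ids, function(pid) {
    ra <- IRanges::reduce(events_ranges(
      rep_events[rep_events$participant_id == pid, ]))
    rb <- IRanges::reduce(events_ranges(
      gps_events[gps_events$participant_id == pid, ]))
    uni <- iv_seconds(IRanges::reduce(c(ra, rb)))
    if (uni == 0) {
      return(tibble::tibble(participant_id = pid, intersection = NA_real_,
                            rep_only = NA_real_, gps_only = NA_real_))
    }
    inter <- iv_seconds(IRanges::intersect(ra, rb))
    rep_only <- iv_seconds(IRanges::setdiff(ra, rb))
    gps_only <- iv_seconds(IRanges::setdiff(rb, ra))
    tibble::tibble(participant_id = pid,
                   intersection = 100 * inter / uni,
                   rep_only = 100 * rep_only / uni,
                   gps_only = 100 * gps_only / uni)
  })
  list(per_participant = per,
       mean = c(intersection = mean(per$intersection, na.rm = TRUE),
                rep_only = mean(per$rep_only, na.rm = TRUE),
                gps_only = mean(per$gps_only, na.rm = TRUE)))
}

#' Descriptive statistics of daily reported-minus-GPS differences
#'
#' Differences are signed REP - GPS, so positive values indicate reports
#' exceeding GPS. Reports the grand mean, sample SD, median, min, max, the
#' between-participant SD (SD of participant mean differences), the mean
#' within-participant SD, and tolerance-band shares: the percentage of days
#' within each tolerance, with REP > GPS beyond it, and with REP < GPS
#' beyond it.
#'
#' @param matched Matched-day tibble (`participant_id, rep, gps, diff`).
#' @param tolerances Numeric tolerances (minutes or counts).
#' @return List of statistics; `tolerance_bands` is a tibble.
#' @export
daily_difference_stats <- function(matched, tolerances = c(10, 20)) {
  d <- matched$diff
  per <- matched |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_diff = mean(.data$diff),
                     sd_within = if (dplyr::n() > 1) sd(.data$diff) else
                       NA_real_,
                     .groups = "drop")
  bands <- purrr::map_dfr(tolerances, function(tol) {
    tibble::tibble(tolerance = tol,
                   pct_agree = 100 * mean(abs(d) <= tol),
                   pct_rep_higher = 100 * mean(d > tol),
                   pct_rep_lower = 100 * mean(d < -tol))
  })
  list(n_days = length(d), mean = mean(d), sd = sd(d), median = median(d),
       min = min(d), max = max(d),
       sd_between = sd(per$mean_diff),
       mean_sd_within = mean(per$sd_within, na.rm = TRUE),
       tolerance_bands = bands)
}

#' Bland-Altman limits of agreement for multiple observations per subject
#'
#' Repeated-measures Bland-Altman where the measurand varies between days:
#' the differences are decomposed by one-way ANOVA over participants into
#' between- and within-participant variance. With group sizes m_i, the
#' effective group size is m0 = (sum m_i - sum m_i^2 / sum m_i) / (n - 1),
#' the between variance is (MSB - MSW) / m0 (truncated at zero), and the
#' total variance of a single difference is their sum. Limits of agreement
#' are the grand mean +/- 1.96 total SD. When every participant contributes
#' one difference this reduces exactly to the simple Bland-Altman limits.
#'
#' @param diff Numeric vector of paired differences (REP - GPS).
#' @param participant_id Grouping vector, same length.
#' @return List `mean_diff, loa_low, loa_high, sd_diff, sigma2_between,
#'   sigma2_within, n_participants, n_obs`.
#' @export
bland_altman_repeated <- function(diff, participant_id) {
  stopifnot(length(diff) == length(participant_id))
  g <- factor(participant_id)
  n <- nlevels(g)
  m <- as.numeric(table(g))
  dbar <- mean(diff)
  if (all(m == 1) || n < 2) {
    s2 <- stats::var(diff)
    sd_d <- sqrt(s2)
    return(list(mean_diff = dbar, loa_low = dbar - 1.96 * sd_d,
                loa_high = dbar + 1.96 * sd_d, sd_diff = sd_d,
                sigma2_between = NA_real_, sigma2_within = NA_real_,
                n_participants = n, n_obs = length(diff)))
  }
  fit <- stats::aov(diff ~ g)
  tab <- summary(fit)[[1]]
  msb <- tab["g", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  m0 <- (sum(m) - sum(m^2) / sum(m)) / (n - 1)
  s2b <- max(0, (msb - msw) / m0)
  s2d <- s2b + msw
  sd_d <- sqrt(s2d)
  list(mean_diff = dbar, loa_low = dbar - 1.96 * sd_d,
       loa_high = dbar + 1.96 * sd_d, sd_diff = sd_d,
       sigma2_between = s2b, sigma2_within = msw,
       n_participants = n, n_obs = length(diff))
}

#' One-way interrater intraclass correlation for paired daily indicators
#'
#' Treats each participant-day as a unit with two measurements (reported
#' and GPS). One-way random-effects ANOVA gives ICC = (MSB - MSW) /
#' (MSB + MSW) for two raters; the 95% confidence interval comes from the
#' F distribution. Zero or negative between-unit variance is reported
#' as-is (ICC can be negative).
#'
#' @param x,y Paired measurements (e.g. reported and GPS daily values).
#' @param conf_level Confidence level for the interval.
#' @return List `icc, ci_low, ci_high, msb, msw, n`.
#' @export
icc_interrater <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need at least 2 participant-days", call. = FALSE)
  k <- 2
  means <- (x + y) / 2
  grand <- mean(c(x, y))
  msb <- k * sum((means - grand)^2) / (n - 1)
  msw <- sum((x - means)^2 + (y - means)^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf_level
  if (msw <= 0) {
    ci <- c(1, 1)
  } else {
    fobs <- msb / msw
    fl <- fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], msb = msb, msw = msw,
       n = n)
}

#' Pooled and within-person Spearman correlations
#'
#' The pooled correlation is computed across all matched participant-days;
#' the within-person correlation (iCorr) is computed per participant over
#' their own days and then summarised as mean and SD across participants.
#' Participants with fewer than `min_days` days or zero variance in either
#' column are dropped from iCorr with a warning.
#'
#' @param matched Matched-day tibble (`participant_id, rep, gps`).
#' @param min_days Minimum days for a participant's iCorr.
#' @return List `pooled, icorr_mean, icorr_sd, per_participant`.
#' @export
mobility_correlations <- function(matched, min_days = 3) {
  pooled <- if (nrow(matched) >= 2) {
    suppressWarnings(cor(matched$rep, matched$gps, method = "spearman"))
  } else NA_real_
  per <- matched |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n = dplyr::n(),
                     v_rep = stats::var(.data$rep),
                     v_gps = stats::var(.data$gps),
                     icorr = if (dplyr::n() >= min_days &&
                                 stats::var(.data$rep) > 0 &&
                                 stats::var(.data$gps) > 0) {
                       cor(.data$rep, .data$gps, method = "spearman")
                     } else NA_real_,
                     .groups = "drop")
  if (any(is.na(per$icorr))) {
    warning("participants without a defined within-person correlation ",
            "dropped from iCorr")
  }
  list(pooled = pooled,
       icorr_mean = mean(per$icorr, na.rm = TRUE),
       icorr_sd = sd(per$icorr, na.rm = TRUE),
       per_participant = per[, c("participant_id", "n", "icorr")])
}

#' Detection rates and overlap by reported event characteristics
#'
#' Groups annotated reported AL events by a label column (activity type or
#' indoor/outdoor): number of events, percentage with at least one matching
#' GPS event, median reported duration and mean overlap fraction. Events
#' labelled "unassignable" contribute counts but no match-rate statistics.
#' Also reports Spearman correlations of reported duration with the
#' matched indicator and with the overlap fraction.
#'
#' @param rep_matches Annotated REP AL events ([match_events()]`$rep`).
#' @param by Name of the label column (`"activity_type"` or
#'   `"indoor_outdoor"`).
#' @return List `table` (tibble) and `duration_correlations`.
#' @export
event_characteristics <- function(rep_matches, by = "activity_type") {
  dur <- duration_min(rep_matches$start, rep_matches$end)
  matched <- as.integer(rep_matches$n_matches >= 1)
  tab <- rep_matches |>
    dplyr::mutate(.dur = dur, .matched = matched) |>
    dplyr::group_by(label = .data[[by]]) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      pct_matched = 100 * mean(.data$.matched),
      median_duration_min = median(.data$.dur),
      mean_overlap_fraction = mean(.data$overlap_fraction),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$pct_matched))
  blank <- tab$label == "unassignable"
  tab$pct_matched[blank] <- NA_real_
  tab$median_duration_min[blank] <- NA_real_
  tab$mean_overlap_fraction[blank] <- NA_real_
  usable <- rep_matches[[by]] != "unassignable"
  dcor <- list(
    duration_vs_matched = suppressWarnings(
      cor(dur[usable], matched[usable], method = "spearman")),
    duration_vs_overlap = suppressWarnings(
      cor(dur[usable], rep_matches$overlap_fraction[usable],
          method = "spearman"))
  )
  list(table = tab, duration_correlations = dcor)
}

#' Full agreement report for one indicator
#'
#' Convenience wrapper computing the event-level (matching, F1, IoU,
#' duration decomposition) and day-level (differences, Bland-Altman, ICC,
#' correlations) statistics on matched valid days.
#'
#' @param matched Matched-day tibble for the indicator.
#' @param rep_events,gps_events Event tibbles (restricted internally to the
#'   matched days).
#' @param tolerances Tolerance bands for [daily_difference_stats()].
#' @return Nested list with all agreement statistics.
#' @export
agreement_report <- function(matched, rep_events, gps_events,
                             tolerances = c(10, 20)) {
  re <- restrict_to_days(rep_events, matched)
  ge <- restrict_to_days(gps_events, matched)
  mt <- match_events(re, ge)
  prf <- precision_recall_f1(mt)
  iou <- suppressWarnings(interval_iou(re, ge))
  dec <- suppressWarnings(duration_decomposition(re, ge))
  ba <- bland_altman_repeated(matched$diff, matched$participant_id)
  icc <- icc_interrater(matched$rep, matched$gps)
  corr <- suppressWarnings(mobility_correlations(matched))
  diffs <- daily_difference_stats(matched, tolerances)
  list(
    matches = mt,
    cardinality = list(rep = summarize_match_cardinality(mt$rep),
                       gps = summarize_match_cardinality(mt$gps)),
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    iou_mean = iou$mean, iou_per_participant = iou$per_participant,
    duration_split = dec$mean,
    daily = diffs, bland_altman = ba, icc = icc, correlations = corr
  )
}
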