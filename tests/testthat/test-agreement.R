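test_that("inclusion rules invalidate contradictory and unworn days", {
  dates <- as.Date("2019-05-06") + 0:4
  rep_daily <- tibble::tibble(
    participant_id = "p1", date = dates,
    rep_toh_min = c(0, 45, 120, 100, 90),
    rep_nals = c(2L, 0L, 1L, 2L, 1L))
  gps_daily <- tibble::tibble(
    participant_id = "p1", date = dates,
    gps_toh_min = c(100, 50, 110, 90, 95),
    gps_nals = c(1L, 1L, 1L, 2L, 1L), gps_valid = TRUE)
  worn <- mk_events(rbind(c(600, 700)))
  worn$worn_flag <- FALSE
  worn$date <- dates[5]
  m <- build_matched_days(rep_daily, gps_daily, worn)
  # day 1: no TOH but ALs -> REP-TOH-invalid; day 5: unworn -> GPS invalid
  expect_setequal(m$toh$date, dates[2:4])
  # day 2: no ALs but 45 > 30 TOH min -> REP-AL-invalid
  expect_setequal(m$al$date, dates[c(1, 3, 4)])

  # a participant with a single matched day is excluded entirely
  m2 <- build_matched_days(rep_daily[3, ], gps_daily[3, ],
                           worn[0, ])
  expect_equal(nrow(m2$toh), 0)
})

test_that("temporal-overlap matching classifies cardinalities", {
  rep_ev <- mk_events(rbind(c(0, 120)))
  gps_ev <- mk_events(rbind(c(10, 50), c(60, 90)), source = "GPS")
  m <- match_events(rep_ev, gps_ev)
  expect_equal(m$rep$cardinality, "1:n")
  expect_equal(m$rep$n_matches, 2L)
  expect_equal(m$gps$cardinality, c("1:1", "1:1"))

  ident <- match_events(rep_ev, mk_events(rbind(c(0, 120)), source = "GPS"))
  expect_equal(ident$rep$cardinality, "1:1")
  expect_equal(ident$rep$overlap_fraction, 1)

  disjoint <- match_events(rep_ev, mk_events(rbind(c(200, 250)),
                                             source = "GPS"))
  expect_equal(disjoint$rep$cardinality, "1:0")
  expect_equal(disjoint$gps$cardinality, "1:0")

  # abutting half-open intervals do not match
  abut <- match_events(rep_ev, mk_events(rbind(c(120, 180)), source = "GPS"))
  expect_equal(abut$rep$n_matches, 0L)

  # overlap fraction of REP [0,60) against GPS [30,90) is 0.5
  half <- match_events(mk_events(rbind(c(0, 60))),
                       mk_events(rbind(c(30, 90)), source = "GPS"))
  expect_equal(half$rep$overlap_fraction, 0.5)

  # cardinality conservation
  tab <- summarize_match_cardinality(m$gps)
  expect_equal(sum(tab$n), nrow(m$gps))
})

test_that("pooled precision, recall and F1 follow the matching counts", {
  rep_ev <- mk_events(rbind(c(0, 60), c(200, 260)))
  gps_ev <- mk_events(rbind(c(30, 90)), source = "GPS")
  prf <- precision_recall_f1(match_events(rep_ev, gps_ev))
  expect_equal(prf$recall, 0.5)
  expect_equal(prf$precision, 1)
  expect_equal(prf$f1, 2 / 3)
  expect_true(prf$f1 >= min(prf$precision, prf$recall) &&
                prf$f1 <= max(prf$precision, prf$recall))

  all_match <- precision_recall_f1(match_events(
    rep_ev, mk_events(rbind(c(0, 60), c(200, 260)), source = "GPS")))
  expect_equal(all_match$f1, 1)

  expect_warning(
    none <- precision_recall_f1(match_events(rep_ev, gps_ev[0, ])),
    "precision undefined")
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
})

test_that("interval IoU matches direct values and the rasterization oracle", {
  rep_ev <- mk_events(rbind(c(0, 60)))
  gps_ev <- mk_events(rbind(c(30, 90)), source = "GPS")
  expect_equal(interval_iou(rep_ev, gps_ev)$mean, 1 / 3)
  expect_equal(interval_iou(rep_ev, rep_ev)$mean, 1)
  expect_equal(interval_iou(rep_ev, mk_events(rbind(c(100, 160)),
                                              source = "GPS"))$mean, 0)
  for (seed in 1:20) {
    es <- random_event_set(seed)
    o <- oracle_iou(es$rep, es$gps)
    if (is.na(o)) next
    expect_equal(suppressWarnings(interval_iou(es$rep, es$gps)$mean), o)
  }
})

test_that("duration decomposition sums to 100 and is consistent with IoU", {
  rep_ev <- mk_events(rbind(c(0, 60)))
  gps_ev <- mk_events(rbind(c(30, 90)), source = "GPS")
  dec <- duration_decomposition(rep_ev, gps_ev)
  expect_equal(unname(dec$mean), rep(100 / 3, 3))
  expect_equal(sum(dec$mean), 100)

  ident <- duration_decomposition(rep_ev, rep_ev)
  expect_equal(unname(ident$mean), c(100, 0, 0))
  disj <- duration_decomposition(rep_ev, mk_events(rbind(c(100, 160)),
                                                   source = "GPS"))
  expect_equal(unname(disj$mean), c(0, 50, 50))

  # cross-operation identity: IoU = intersection share of the union
  for (seed in 21:30) {
    es <- random_event_set(seed)
    if (nrow(es$rep) == 0 && nrow(es$gps) == 0) next
    dec_i <- duration_decomposition(es$rep, es$gps)
    iou_i <- suppressWarnings(interval_iou(es$rep, es$gps)$mean)
    expect_equal(iou_i, unname(dec_i$mean["intersection"]) / 100)
  }
})

test_that("daily difference statistics use the sample-SD conventions", {
  m <- tibble::tibble(participant_id = c("a", "a", "b", "b"),
                      rep = c(20, 10, 0, 10), gps = c(10, 0, 10, 20)) |>
    dplyr::mutate(diff = rep - gps)
  s <- daily_difference_stats(m, tolerances = c(10, 20))
  # participants with constant differences +10 and -10
  expect_equal(s$mean, 0)
  expect_equal(s$sd_between, sd(c(10, -10)))  # 14.14 under sample SD
  expect_equal(s$mean_sd_within, 0)

  one <- tibble::tibble(participant_id = "a", rep = c(5, 0), gps = c(0, 5)) |>
    dplyr::mutate(diff = rep - gps)
  s1 <- daily_difference_stats(one)
  expect_equal(s1$mean, 0)
  expect_equal(s1$mean_sd_within, sd(c(5, -5)))  # 7.07

  zero <- tibble::tibble(participant_id = c("a", "b"), rep = c(1, 2),
                         gps = c(1, 2), diff = c(0, 0))
  s0 <- daily_difference_stats(zero, tolerances = c(0, 10))
  expect_equal(s0$sd, 0)
  expect_equal(s0$tolerance_bands$pct_agree, c(100, 100))
})

test_that("repeated-measures limits of agreement follow the ANOVA decomposition", {
  # all differences equal -> zero-width limits
  const <- bland_altman_repeated(rep(3, 6), rep(c("a", "b"), each = 3))
  expect_equal(const$mean_diff, 3)
  expect_equal(const$loa_low, 3)
  expect_equal(const$loa_high, 3)

  # one observation per participant reduces to simple Bland-Altman
  set.seed(1)
  d <- rnorm(12)
  simple <- bland_altman_repeated(d, paste0("p", 1:12))
  expect_equal(simple$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(simple$loa_high, mean(d) + 1.96 * sd(d))

  # balanced toy table: the ANOVA route equals the hand-computed one
  set.seed(2)
  id <- rep(letters[1:3], each = 4)
  d2 <- rnorm(12, rep(c(-2, 0, 2), each = 4), 1)
  ba <- bland_altman_repeated(d2, id)
  fit <- stats::anova(stats::lm(d2 ~ factor(id)))
  msb <- fit$`Mean Sq`[1]; msw <- fit$`Mean Sq`[2]
  m0 <- (12 - sum(rep(4, 3)^2) / 12) / 2
  s2d <- max(0, (msb - msw) / m0) + msw
  expect_equal(ba$sd_diff, sqrt(s2d))
  expect_equal(ba$loa_high - ba$mean_diff, 1.96 * sqrt(s2d))
})

test_that("the one-way ICC behaves at its reference points", {
  x <- c(1, 5, 9, 13, 2)
  ident <- icc_interrater(x, x)
  expect_equal(ident$icc, 1)

  # location invariance under a shared shift
  y <- x + c(0.5, -0.5, 1, -1, 0)
  base <- icc_interrater(x, y)
  shifted <- icc_interrater(x + 100, y + 100)
  expect_equal(base$icc, shifted$icc)
  expect_equal(base$ci_low, shifted$ci_low)

  # crossed toy table with equal means: near-zero agreement, checked
  # against an independent ANOVA fit
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  res <- icc_interrater(a, b)
  long <- data.frame(y = c(a, b), unit = factor(rep(1:4, 2)))
  tab <- stats::anova(stats::lm(y ~ unit, data = long))
  msb <- tab$`Mean Sq`[1]; msw <- tab$`Mean Sq`[2]
  expect_equal(res$icc, (msb - msw) / (msb + msw))
  expect_lt(abs(res$icc), 0.2)
})

test_that("pooled and within-person Spearman correlations", {
  m <- tibble::tibble(participant_id = rep("a", 5), rep = 1:5,
                      gps = c(1, 2, 3, 5, 4))
  res <- suppressWarnings(mobility_correlations(m))
  expect_equal(res$pooled, 1 - 6 * 2 / (5 * 24))  # rank formula: 0.9
  expect_equal(res$icorr_mean, 0.9)

  perfect <- tibble::tibble(participant_id = rep(c("a", "b"), each = 4),
                            rep = rep(1:4, 2), gps = rep(2:5, 2))
  resp <- mobility_correlations(perfect)
  expect_equal(resp$pooled, 1)
  expect_equal(resp$icorr_mean, 1)
  expect_equal(resp$icorr_sd, 0)

  rev <- tibble::tibble(participant_id = "a", rep = 1:4, gps = 4:1)
  expect_equal(suppressWarnings(mobility_correlations(rev))$pooled, -1)

  # degenerate participants are dropped with a warning
  flat <- tibble::tibble(participant_id = rep(c("a", "b"), each = 3),
                         rep = c(1, 2, 3, 1, 1, 1), gps = c(1, 2, 3, 4, 5, 6))
  expect_warning(resf <- mobility_correlations(flat), "dropped")
  expect_equal(resf$icorr_mean, 1)
})

test_that("event characteristics summarise detection by category", {
  rep_ev <- dplyr::bind_rows(
    mk_events(rbind(c(0, 60), c(100, 160))),
    mk_events(rbind(c(300, 330)))
  )
  rep_ev$activity_type <- c("recreation", "recreation", "unassignable")
  rep_ev$indoor_outdoor <- c("indoor", "outdoor", "indoor")
  gps_ev <- mk_events(rbind(c(30, 90)), source = "GPS")
  ann <- match_events(rep_ev, gps_ev)$rep
  chars <- event_characteristics(ann, by = "activity_type")
  rec <- chars$table[chars$table$label == "recreation", ]
  expect_equal(rec$n_events, 2L)
  expect_equal(rec$pct_matched, 50)
  expect_equal(rec$mean_overlap_fraction, 0.25)
  una <- chars$table[chars$table$label == "unassignable", ]
  expect_equal(una$n_events, 1L)
  expect_true(is.na(una$pct_matched))
  expect_true(is.numeric(chars$duration_correlations$duration_vs_matched))
})

test_that("agreement statistics are invariant to participant relabelling", {
  set.seed(3)
  m <- tibble::tibble(
    participant_id = rep(c("a", "b", "c"), each = 4),
    rep = rnorm(12, 100, 20), gps = rnorm(12, 100, 20)) |>
    dplyr::mutate(diff = rep - gps)
  relab <- m
  relab$participant_id <- chartr("abc", "zyx", relab$participant_id)
  relab <- relab[sample(1:12), ]
  b1 <- bland_altman_repeated(m$diff, m$participant_id)
  b2 <- bland_altman_repeated(relab$diff, relab$participant_id)
  expect_equal(b1$loa_low, b2$loa_low)
  expect_equal(icc_interrater(m$rep, m$gps)$icc,
               icc_interrater(relab$rep, relab$gps)$icc)
  expect_equal(mobility_correlations(m)$icorr_mean,
               mobility_correlations(relab)$icorr_mean)
})
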