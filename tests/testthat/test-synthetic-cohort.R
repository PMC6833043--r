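test_that("configuration validation names the offending field", {
  expect_error(sim_config(indoor_loss_prob = 1.2), "indoor_loss_prob")
  expect_error(sim_config(gps_interval = 0), "gps_interval")
  expect_error(sim_config(outings_per_day_mean = -1), "outings_per_day_mean")
  expect_error(simulate_cohort(list()), "config")
})

test_that("equal configurations (including seed) give identical cohorts", {
  cfg <- sim_config(n_participants = 2, n_days = 3, gps_interval = 60,
                    seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(sim_config(n_participants = 2, n_days = 3,
                                   gps_interval = 60, seed = 6))
  expect_false(identical(c1$fixes, c3$fixes))
})

test_that("error-free limit: diaries equal truth and fixes lie on the path", {
  cfg <- sim_config_errorfree(n_participants = 2, n_days = 3,
                              gps_interval = 30, seed = 3)
  coh <- simulate_cohort(cfg)
  expect_equal(coh$toh_diary$start, coh$truth$toh$start)
  expect_equal(coh$toh_diary$end, coh$truth$toh$end)
  expect_equal(coh$al_diary$start, coh$truth$al$start)
  expect_true(all(coh$toh_diary$worn_flag))
  # stationary periods: every fix during a true visit sits exactly at the
  # visit position
  al <- coh$truth$al[1, ]
  fx <- coh$fixes[coh$fixes$participant_id == al$participant_id &
                    coh$fixes$timestamp >= al$start &
                    coh$fixes$timestamp < al$end, ]
  expect_gt(nrow(fx), 0)
  expect_true(all(oracle_dist_m(fx$lat, fx$lon, al$lat, al$lon) < 0.01))
})

test_that("ground-truth invariants: visits nested in outings, no overlap", {
  coh <- simulate_cohort(sim_config(n_participants = 3, n_days = 5,
                                    gps_interval = 60, seed = 9))
  toh <- coh$truth$toh
  al <- coh$truth$al
  for (i in seq_len(nrow(al))) {
    host <- toh[toh$participant_id == al$participant_id[i] &
                  toh$start <= al$start[i] & toh$end >= al$end[i], ]
    expect_equal(nrow(host), 1)
  }
  overlaps <- toh |>
    dplyr::group_by(participant_id, date) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(ok = all(diff(as.numeric(start)) >= 0) &&
                       (dplyr::n() < 2 ||
                          all(utils::head(end, -1) <= utils::tail(start, -1))),
                     .groups = "drop")
  expect_true(all(overlaps$ok))
})

test_that("full omission empties the diaries but not the truth", {
  cfg <- sim_config(n_participants = 2, n_days = 4, gps_interval = 60,
                    diary_omission_prob = 1, diary_spurious_prob = 0,
                    seed = 2)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$toh_diary), 0)
  expect_equal(nrow(coh$al_diary), 0)
  expect_gt(nrow(coh$truth$toh), 0)
})

test_that("fixture files round-trip through the pipeline readers", {
  cfg <- sim_config_errorfree(n_participants = 1, n_days = 1,
                              gps_interval = 60, seed = 4)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "gps_fixes.csv", "toh_diary.csv", "al_diary.csv", "homes.csv",
    "ground_truth.json")))))
  back <- read_cohort(dir)
  expect_equal(back$fixes$timestamp, coh$fixes$timestamp)
  expect_equal(back$fixes$lat, coh$fixes$lat, tolerance = 1e-9)
  expect_equal(back$toh_diary$start, coh$toh_diary$start)
  expect_equal(back$al_diary$activity_type, coh$al_diary$activity_type)
  expect_equal(back$homes$lat, coh$homes$lat, tolerance = 1e-9)
})

test_that("an empty cohort still writes schema-valid files", {
  coh <- simulate_cohort(sim_config(n_participants = 0, n_days = 2,
                                    seed = 1))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$fixes), 0)
  expect_equal(nrow(back$toh_diary), 0)
})

test_that("AL F1 degrades as diary omission grows (averaged over seeds)", {
  f1_at <- function(om, seed) {
    cfg <- sim_config_errorfree(n_participants = 3, n_days = 4,
                                gps_interval = 60,
                                diary_omission_prob = om, seed = seed)
    coh <- simulate_cohort(cfg)
    res <- run_pipeline(coh, pipeline_config(
      thresholds = thresholds_errorfree()))
    res$reports$al$f1
  }
  seeds <- 1:20
  means <- vapply(c(0, 0.25, 0.5), function(om) {
    mean(vapply(seeds, function(s) f1_at(om, s), numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
  expect_equal(means[1], 1)
})
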