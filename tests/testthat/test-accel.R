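# Event-log processing: wear-day validity, cadence classification, daily
# summaries and their conservation properties.

test_that("wear-day validity rules: first day, short final day, short middle day", {
  # 8 days of 15.5 h waking: day 1 dropped, final day kept (15.5 > 14 h)
  v <- select_valid_days(wake_fixture(rep(15.5, 8)))
  expect_equal(v$days$day_index[v$days$valid], 2:8)
  expect_length(v$excluded, 0)

  # final day with 13 h waking is excluded (<= 14 h)
  v <- select_valid_days(wake_fixture(c(rep(15.5, 7), 13)))
  expect_equal(v$days$day_index[v$days$valid], 2:7)
  expect_equal(v$days$reason[v$days$day_index == 8], "final_day_short")

  # a middle day with 9 h waking is invalid (< 10 h)
  hrs <- rep(15.5, 8); hrs[4] <- 9
  v <- select_valid_days(wake_fixture(hrs))
  expect_false(v$days$valid[v$days$day_index == 4])
  expect_equal(v$days$reason[v$days$day_index == 4], "short_day")

  # exactly 14 h on the final day is still excluded; exactly 10 h mid-week is valid
  v <- select_valid_days(wake_fixture(c(15.5, 10, rep(15.5, 5), 14)))
  expect_false(v$days$valid[v$days$day_index == 8])
  expect_true(v$days$valid[v$days$day_index == 2])
})

test_that("participants with no valid day are flagged excluded, not errored", {
  v <- select_valid_days(wake_fixture(c(15.5, 9, 9)))
  expect_equal(v$excluded, "W1")
  # raising the minimum number of valid days excludes borderline participants
  v2 <- select_valid_days(wake_fixture(c(15.5, 15, 9)), min_valid_days = 2)
  expect_equal(v2$excluded, "W1")
})

test_that("cadence classification: strict > 110 steps/min boundary", {
  expect_equal(classify_bout("step", 1200, 600), "HPA")   # 120 steps/min
  expect_equal(classify_bout("step", 1100, 600), "LPA")   # exactly 110
  expect_equal(classify_bout("step", 1101, 600), "HPA")   # just above
  expect_equal(classify_bout("sed", 0, 36000), "ST")      # any-length sit/lie
  expect_equal(classify_bout("stand", 0, 300), "standing")
  expect_error(classify_bout("step", 10, 0), "duration")
  # vectorized
  expect_equal(classify_bout(c("sed", "step"), c(0, 300), c(60, 120)),
               c("ST", "HPA"))
})

test_that("summaries echo a single valid day and average over several", {
  fx <- single_day_fixture(st_min = 540, stand_min = 281, lpa_min = 100,
                           hpa_min = 24)
  s <- summarize_activity(fx$bouts, fx$wake,
                          validity = list(days = data.frame(
                            participant_id = "X1", day_index = 2,
                            wake_min = 945, valid = TRUE, reason = ""),
                            excluded = character(0)))
  expect_equal(s$st_min_day, 540)
  expect_equal(s$lpa_min_day, 100)
  expect_equal(s$hpa_min_day, 24)
  expect_equal(s$total_pa_min_day, 124)
  expect_equal(s$wake_min_day, 945)

  # two valid days with ST 500 and 580 average to 540
  f1 <- single_day_fixture(500, 200, 80, 20, day = 2)
  f2 <- single_day_fixture(580, 200, 80, 20, day = 3)
  bouts <- rbind(f1$bouts, f2$bouts)
  wake <- rbind(f1$wake, f2$wake)
  val <- list(days = data.frame(participant_id = "X1", day_index = 2:3,
                                wake_min = 800, valid = TRUE, reason = ""),
              excluded = character(0))
  s <- summarize_activity(bouts, wake, validity = val)
  expect_equal(s$st_min_day, 540)
  expect_equal(s$n_valid_days, 2)
})

test_that("bouts straddling the wake boundary are truncated with prorated steps", {
  # a 20-min LPA bout straddles wake start by 10 min: only 10 min count
  bouts <- data.frame(participant_id = "X1", day_index = 2,
                      start_s = c(6 * 3600 - 600, 6 * 3600 + 600),
                      duration_s = c(1200, 3600 - 1200 - 600),
                      posture = c("step", "sed"),
                      steps = c(1800, 0))  # cadence 90/min
  wake <- data.frame(participant_id = "X1", day_index = 2,
                     wake_start_s = 6 * 3600, wake_end_s = 7 * 3600)
  val <- list(days = data.frame(participant_id = "X1", day_index = 2,
                                wake_min = 60, valid = TRUE, reason = ""),
              excluded = character(0))
  s <- summarize_activity(bouts, wake, validity = val)
  expect_equal(s$lpa_min_day, 10)  # truncated portion, still LPA at 90/min
  expect_equal(s$st_min_day, 30)
  expect_equal(s$wake_min_day, 60)
})

test_that("summaries match the per-second brute-force oracle on generated logs", {
  co <- generate_cohort(synth_config(n_participants = 4, n_regions = 6,
                                     seed = 42))
  val <- select_valid_days(co$wake_windows)
  s <- summarize_activity(co$events, co$wake_windows, validity = val)
  vd <- val$days[val$days$valid, ]
  orc <- oracle_summary(co$events, co$wake_windows, vd)
  agg <- aggregate(orc[, c("st", "standing", "lpa", "hpa", "wake")],
                   by = list(participant_id = orc$participant_id), FUN = mean)
  agg <- agg[match(s$participant_id, agg$participant_id), ]
  expect_equal(s$st_min_day, agg$st, tolerance = 1e-9)
  expect_equal(s$standing_min_day, agg$standing, tolerance = 1e-9)
  expect_equal(s$lpa_min_day, agg$lpa, tolerance = 1e-9)
  expect_equal(s$hpa_min_day, agg$hpa, tolerance = 1e-9)
  expect_equal(s$wake_min_day, agg$wake, tolerance = 1e-9)
})

test_that("daily time budget is conserved and stepping splits into LPA + HPA", {
  co <- generate_cohort(synth_config(n_participants = 6, n_regions = 6,
                                     seed = 11))
  s <- summarize_activity(co$events, co$wake_windows)
  budget <- s$st_min_day + s$standing_min_day + s$lpa_min_day + s$hpa_min_day
  expect_equal(budget, s$wake_min_day, tolerance = 1 / 60)  # 1 s accumulation
  expect_equal(s$total_pa_min_day, s$lpa_min_day + s$hpa_min_day)
  expect_true(all(s$st_min_day + s$lpa_min_day + s$hpa_min_day <=
                    s$wake_min_day + 1e-9))
})

test_that("adding a high-cadence bout raises HPA and leaves ST unchanged", {
  fx <- single_day_fixture(500, 200, 80, 20)
  val <- list(days = data.frame(participant_id = "X1", day_index = 2,
                                wake_min = 800, valid = TRUE, reason = ""),
              excluded = character(0))
  base <- summarize_activity(fx$bouts, fx$wake, validity = val)
  # extend the wake window and append a 10-min bout at 130 steps/min
  wake2 <- fx$wake
  wake2$wake_end_s <- wake2$wake_end_s + 600
  extra <- data.frame(participant_id = "X1", day_index = 2,
                      start_s = max(fx$bouts$start_s + fx$bouts$duration_s),
                      duration_s = 600, posture = "step", steps = 1300)
  val2 <- val; val2$days$wake_min <- 810
  more <- summarize_activity(rbind(fx$bouts, extra), wake2, validity = val2)
  expect_gt(more$hpa_min_day, base$hpa_min_day)
  expect_equal(more$st_min_day, base$st_min_day)
})

test_that("exposure inversion negates, is an involution, and skips ST", {
  expect_equal(invert_exposure(c(124, 100, 24)), c(-124, -100, -24))
  x <- rnorm(10)
  expect_equal(invert_exposure(invert_exposure(x)), x)
  d <- data.frame(total_pa_min_day = 124, lpa_min_day = 100,
                  hpa_min_day = 24, st_min_day = 558)
  d <- add_inverted_exposures(d)
  expect_equal(d$hpa_inv, -24)
  expect_equal(d$st_min_day, 558)  # sedentary time is never inverted
})

test_that("guideline stratification uses an inclusive 150/7 min/day boundary", {
  expect_true(guideline_stratify(39))
  expect_false(guideline_stratify(11))
  expect_true(guideline_stratify(150 / 7))
  expect_false(guideline_stratify(150 / 7 - 1e-9))
  expect_equal(GUIDELINE_HPA_MIN_PER_DAY, 150 / 7)
})

test_that("bout validation rejects malformed logs", {
  b <- data.frame(participant_id = "A", day_index = 1, start_s = 0,
                  duration_s = 60, posture = "sed", steps = 5)
  expect_error(validate_bouts(b), "steps must be 0")
  b2 <- data.frame(participant_id = "A", day_index = 1,
                   start_s = c(0, 30), duration_s = c(60, 60),
                   posture = "sed", steps = 0)
  expect_error(validate_bouts(b2), "overlapping")
})
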