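test_that("active-period detection applies threshold, merge and minimum bout", {
  rate <- 10
  quiet <- rep(0.01, 300)
  expect_equal(nrow(detect_active(quiet, rate, threshold = 0.04)), 0)

  one <- c(rep(0, 100), rep(0.1, 100), rep(0, 100))
  iv <- detect_active(one, rate, threshold = 0.04)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$end_s - iv$start_s, 10)

  # two runs separated by more than the merge gap stay separate; a short
  # gap merges — checked against a run-length oracle on the sample mask
  x <- c(rep(0.1, 50), rep(0, 40), rep(0.1, 50), rep(0, 5), rep(0.1, 50))
  iv2 <- detect_active(x, rate, threshold = 0.04, merge_gap_s = 2)
  expect_equal(nrow(iv2), 2)
  expect_equal(iv2$end_s[2] - iv2$start_s[2], 10.5)   # 5+0.5+5 s merged

  expect_error(detect_active(x, rate, threshold = 0), "positive")
})

test_that("active detection is idempotent on its own indicator signal", {
  rate <- 10
  set.seed(3)
  x <- abs(rnorm(600, 0, 0.05))
  iv <- detect_active(x, rate, threshold = 0.05, min_bout_s = 1,
                      merge_gap_s = 2)
  indicator <- rep(0, 600)
  for (i in seq_len(nrow(iv))) {
    indicator[(round(iv$start_s[i] * rate) + 1):round(iv$end_s[i] * rate)] <- 1
  }
  iv2 <- detect_active(indicator, rate, threshold = 0.5, min_bout_s = 1,
                       merge_gap_s = 2)
  expect_equal(iv2$start_s, iv$start_s, tolerance = 1e-9)
  expect_equal(iv2$end_s, iv$end_s, tolerance = 1e-9)
})

test_that("walking detection needs repetitive peaks at a plausible cadence", {
  rate <- 50
  flat <- rep(1, 1000)
  expect_equal(nrow(detect_walking(flat, rate)), 0)

  # 10 step peaks at 2 Hz
  t <- (0:1499) / rate
  x <- rep(1, 1500)
  for (s in seq(10, by = 0.5, length.out = 10)) {
    j <- which(t >= s & t < s + 0.2)
    x[j] <- x[j] + 0.3 * 0.5 * (1 - cos(2 * pi * (t[j] - s) / 0.2))
  }
  bouts <- detect_walking(x, rate)
  expect_equal(nrow(bouts), 1)
  expect_equal(bouts$step_count, 10)
  expect_true(bouts$start_s < 10.2 && bouts$end_s > 14.5)

  # a single isolated peak is not walking (minimum of 2 steps)
  x1 <- rep(1, 1500)
  j <- which(t >= 10 & t < 10.2)
  x1[j] <- x1[j] + 0.4 * 0.5 * (1 - cos(2 * pi * (t[j] - 10) / 0.2))
  expect_equal(nrow(detect_walking(x1, rate)), 0)
})

test_that("lying detection requires sustained tilt beyond the threshold", {
  rate <- 50
  upright <- rep(2, 3000)             # degrees
  expect_equal(nrow(detect_lying(upright, rate)), 0)

  x <- c(rep(2, 500), rep(85, 1500), rep(2, 500))
  iv <- detect_lying(x, rate, angle_threshold_deg = 60, min_duration_s = 10)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$end_s - iv$start_s, 30)

  short <- c(rep(2, 500), rep(85, 150), rep(2, 500))   # 3 s only
  expect_equal(nrow(detect_lying(short, rate, 60, 10)), 0)
})

test_that("candidate windows appear at transfers and nowhere else", {
  # quiet sitting: no candidates
  run <- standardized_run(5)
  quiet <- quiet_recording(30)
  der_q <- derive_signals(quiet)
  expect_equal(nrow(candidate_transfers(der_q)), 0)

  # a single synthetic stand-up at a known time
  prof <- make_profile(FALSE, 5)
  b <- tolsense:::script_builder()
  b$add("sitting", 28, "x"); b$add("sit_to_stand", 2, "x"); b$add("standing", 20, "x")
  sc <- tolsense:::as_protocol_script(b)
  syn <- synthesize(sc, prof, noise_std_g = 0, seed = 5)
  der <- derive_signals(syn$recording)
  cand <- candidate_transfers(der)
  expect_equal(nrow(cand), 1)
  expect_true(cand$win_start_s < 29 && cand$win_end_s > 29)  # contains t=29

  # two transients 20 s apart give two windows
  b2 <- tolsense:::script_builder()
  b2$add("sitting", 10, "x"); b2$add("sit_to_stand", 2, "x")
  b2$add("standing", 18, "x"); b2$add("stand_to_sit", 2, "x")
  b2$add("sitting", 10, "x")
  syn2 <- synthesize(tolsense:::as_protocol_script(b2), prof,
                     noise_std_g = 0, seed = 6)
  expect_equal(nrow(candidate_transfers(derive_signals(syn2$recording))), 2)
})

test_that("transfer features behave at the fixed points", {
  tmpl <- transfer_template(50, 2.5)
  expect_equal(max(abs(tmpl)), 1)
  expect_equal(attr(tmpl, "version"), "1.0")

  # a window identical to the template correlates perfectly
  prof <- make_profile(FALSE, 8)
  b <- tolsense:::script_builder()
  b$add("sitting", 10, "x"); b$add("sit_to_stand", 2.5, "x"); b$add("standing", 10, "x")
  syn <- synthesize(tolsense:::as_protocol_script(b), prof, noise_std_g = 0, seed = 8)
  der <- derive_signals(syn$recording)
  cand <- candidate_transfers(der)
  fe <- transfer_features(as.list(cand[1, ]), der, tmpl)
  expect_gt(fe[["template_xcorr"]], 0.9)
  expect_equal(fe[["altitude_delta_m"]], prof$seat_height_m, tolerance = 0.1)
  expect_gte(fe[["peak_valley_dt"]], 0)

  # flat window: zero correlation, zero altitude change
  derq <- derive_signals(quiet_recording(20))
  win <- list(centre_s = 10, start_s = 9, end_s = 11,
              win_start_s = 8.25, win_end_s = 11.75, altitude_delta_m = NULL)
  feq <- transfer_features(win, derq, tmpl)
  expect_equal(feq[["template_xcorr"]], 0, tolerance = 1e-6)
  expect_equal(feq[["altitude_delta_m"]], 0, tolerance = 1e-6)

  # window shorter than the template is a feature error
  win_short <- list(centre_s = 10, start_s = 9.8, end_s = 10.2,
                    win_start_s = 9.5, win_end_s = 10.5, altitude_delta_m = NULL)
  expect_error(transfer_features(win_short, derq, tmpl), "feature error")
})

test_that("transfer classification separates directions and rejects junk", {
  m <- cached_svm()
  run <- standardized_run(3, model = m)
  # the pipeline recovered both transfer directions on a clean recording
  expect_gt(nrow(run$cls$detections$sit_to_stand), 0)
  expect_gt(nrow(run$cls$detections$stand_to_sit), 0)

  zero <- structure(setNames(rep(0, 6),
                             c("template_xcorr", "peak_valley_dt",
                               "orientation_deg", "intensity_before",
                               "intensity_after", "altitude_delta_m")),
                    class = "transfer_features")
  expect_equal(classify_transfer(zero, m), "none")
  expect_equal(classify_transfer(zero, transfer_threshold_model()), "none")
  expect_error(classify_transfer(zero, NULL), "state error")
})

test_that("the margin classifier holds on held-out synthetic features", {
  m <- cached_svm()
  held_out <- make_transfer_training_set(n_per_class = 20, seed = 424242)
  acc <- mean(predict(m, held_out[-1]) == as.character(held_out$label))
  expect_gte(acc, 0.95)
  # mirrored physics: stand-to-sit features carry the opposite altitude sign
  sts <- held_out[held_out$label == "sit_to_stand", ]
  stn <- held_out[held_out$label == "stand_to_sit", ]
  expect_true(all(sts$altitude_delta_m > 0))
  expect_true(all(stn$altitude_delta_m < 0))
})
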