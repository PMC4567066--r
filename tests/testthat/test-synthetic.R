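test_that("profiles respect the frailty rule and are reproducible", {
  pf <- make_profile(TRUE, 1)
  expect_true(pf$frail)
  expect_gte(pf$gfi_score, 4)
  pn <- make_profile(FALSE, 1)
  expect_false(pn$frail)
  expect_lte(pn$gfi_score, 3)
  expect_identical(make_profile(TRUE, 7), make_profile(TRUE, 7))
  expect_true(pf$uses_walking_aid)       # all frail subjects use an aid
})

test_that("frail cadence sits below non-frail cadence by construction", {
  cf <- vapply(1:100, function(s) make_profile(TRUE, s)$cadence_hz, 0)
  cn <- vapply(1:100, function(s) make_profile(FALSE, s)$cadence_hz, 0)
  expect_lt(max(cf), min(cn))
  expect_lt(mean(cf), mean(cn))
})

test_that("the standardized script realizes the protocol in order", {
  pf <- make_profile(FALSE, 3)
  sc <- script_standardized(pf)
  # first item: standing still in front of the chair for 5 seconds
  expect_equal(sc$label[1], "standing")
  expect_equal(sc$end_s[1] - sc$start_s[1], 5)
  # chair-rise block: exactly 10 transfer events (5 rises + 5 descents)
  cr <- sc[sc$phase == "chair_rise", ]
  expect_equal(sum(cr$label %in% c("sit_to_stand", "stand_to_sit")), 10)
  # contiguity from zero
  expect_equal(sc$start_s[1], 0)
  expect_equal(sc$start_s[-1], sc$end_s[-nrow(sc)])

  # the aided walk appears only for aid users
  aid <- make_profile(TRUE, 3)       # frail profiles always use an aid
  expect_true("aided_walk" %in% script_standardized(aid)$phase)
  no_aid <- make_profile(FALSE, 3)
  if (!no_aid$uses_walking_aid) {
    expect_false("aided_walk" %in% script_standardized(no_aid)$phase)
  }
})

test_that("free-movement scripts are exact-length semi-Markov sequences", {
  pf <- make_profile(FALSE, 4)
  sc <- script_free(pf, duration_s = 600, seed = 4)
  expect_equal(max(sc$end_s), 600)
  expect_equal(sc$start_s[-1], sc$end_s[-nrow(sc)])
  expect_identical(script_free(pf, 600, 4), script_free(pf, 600, 4))

  # every sitting -> standing boundary carries a sit_to_stand event
  lab <- sc$label
  for (i in seq_len(length(lab) - 1)) {
    if (lab[i] == "sitting" && lab[i + 1] %in% c("standing", "walking")) {
      fail("sitting followed directly by upright activity without a transfer")
    }
    if (lab[i] == "sit_to_stand") expect_equal(lab[i + 1], "standing")
  }
})

test_that("synthesis honours the sampling contract and the seed", {
  pf <- make_profile(FALSE, 6)
  b <- tolsense:::script_builder()
  b$add("sitting", 20, "x"); b$add("sit_to_stand", 2, "x")
  b$add("standing", 10, "x"); b$add("walking", 18, "x")
  b$add("standing", 10, "x")
  sc <- tolsense:::as_protocol_script(b)           # 60 s total
  syn <- synthesize(sc, pf, noise_std_g = 0.05, seed = 6)
  expect_equal(nrow(syn$recording$accel_xyz), 3000)   # 60 s x 50 Hz
  expect_equal(length(syn$recording$pressure), 1500)  # 60 s x 25 Hz

  syn2 <- synthesize(sc, pf, noise_std_g = 0.05, seed = 6)
  expect_identical(syn$recording$accel_xyz, syn2$recording$accel_xyz)
  expect_identical(syn$recording$pressure, syn2$recording$pressure)
})

test_that("zero-noise lying segments exceed the lying tilt threshold", {
  pf <- make_profile(FALSE, 2)
  b <- tolsense:::script_builder()
  b$add("standing", 10, "x"); b$add("lying", 30, "x"); b$add("standing", 10, "x")
  syn <- synthesize(tolsense:::as_protocol_script(b), pf,
                    noise_std_g = 0, seed = 2)
  der <- derive_signals(syn$recording)
  mid <- which(der$accel_time > 15 & der$accel_time < 35)
  expect_true(all(der$tilt_deg[mid] > 60))
})

test_that("scripted category totals equal annotation category totals", {
  for (s in c(1, 8)) {
    pf <- make_profile(s %% 2 == 0, s)
    sc <- script_standardized(pf)
    tr <- collapse_to_video_track(sc)
    # collapse assigns transfers to the destination posture
    collapse <- function(lab) {
      lab[lab == "sit_to_stand"] <- "standing"
      lab[lab == "stand_to_sit"] <- "sitting"
      lab
    }
    want <- tapply(sc$end_s - sc$start_s, collapse(sc$label), sum)
    got <- tapply(tr$end_s - tr$start_s, tr$label, sum)
    expect_equal(got[order(names(got))], want[order(names(want))],
                 tolerance = 1e-9)
  }
})

test_that("each detector recovers its own kind on zero-noise output", {
  # shared consistency contract between the generator and the detectors
  for (s in c(3, 10)) {
    run <- standardized_run(s, frail = s %% 2 == 0)
    sc <- run$script
    der <- derive_signals(run$syn$recording)
    nsec <- run$cls$duration_s
    truth <- label_chr(run$ref)

    cover <- function(det, n) {
      mask <- rep(FALSE, n)
      for (i in seq_len(nrow(det))) {
        lo <- max(1, floor(det$start_s[i]) + 1)
        hi <- min(n, ceiling(det$end_s[i]))
        mask[lo:hi] <- TRUE
      }
      mask
    }
    recovery <- function(kind, truth_mask) {
      det <- run$cls$detections[[kind]]
      sum(cover(det, nsec) & truth_mask) / sum(truth_mask)
    }
    expect_gte(recovery("walking", truth == "walking"), 0.9)
    expect_gte(recovery("lying", truth == "lying"), 0.9)
    both <- cover(run$cls$detections$sit_to_stand, nsec) |
      cover(run$cls$detections$stand_to_sit, nsec)
    tmask <- truth %in% c("sit_to_stand", "stand_to_sit")
    expect_gte(sum(both & tmask) / sum(tmask), 0.9)
    # movement seconds (walking + transfers) register as active
    active_truth <- truth %in% c("walking", "sit_to_stand", "stand_to_sit")
    expect_gte(recovery("active", active_truth), 0.9)
  }
})
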