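#' Synthetic subject profile
#'
#' Draws the kinematic parameters of a simulated older adult.  Frailty
#' follows the 15-item Groningen Frailty Indicator convention: a total score
#' of 4 or more classifies a subject as frail.  Frail profiles walk with a
#' slower cadence, smaller step peaks, larger sway and slower transfers, and
#' always use a walking aid (introducing step asymmetry); non-frail profiles
#' use an aid rarely.
#'
#' @param frail logical: draw a frail profile?
#' @param seed integer seed; the draw is reproducible.
#' @return a `subject_profile` list with fields `gfi_score`, `frail`,
#'   `cadence_hz`, `step_peak_g`, `sway_std_g`, `transfer_duration_s`,
#'   `seat_height_m`, `uses_walking_aid`, `aid_asymmetry`, `speed_factor`,
#'   `floor_lie`, `lying_tilt_deg`.
#' @export
make_profile <- function(frail, seed) {
  with_seed(seed, {
    gfi <- if (frail) sample(4:15, 1L) else sample(0:3, 1L)
    uses_aid <- if (frail) TRUE else runif(1) < 2 / 13
    p <- list(
      gfi_score = gfi,
      frail = gfi >= 4L,
      cadence_hz = if (frail) runif(1, 1.0, 1.4) else runif(1, 1.5, 2.0),
      step_peak_g = if (frail) runif(1, 0.20, 0.35) else runif(1, 0.30, 0.50),
      sway_std_g = if (frail) runif(1, 0.03, 0.06) else runif(1, 0.01, 0.03),
      transfer_duration_s = if (frail) runif(1, 2.2, 3.0) else runif(1, 1.5, 2.2),
      seat_height_m = 0.45,
      uses_walking_aid = uses_aid,
      aid_asymmetry = if (uses_aid) runif(1, 0.2, 0.4) else 0,
      speed_factor = if (frail) runif(1, 1.3, 1.6) else 1,
      floor_lie = if (frail) FALSE else runif(1) < 0.8,
      lying_tilt_deg = runif(1, 80, 95)
    )
    structure(p, class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> GFI %d (%s) | cadence %.2f Hz | transfer %.1f s | aid: %s\n",
              x$gfi_score, if (x$frail) "frail" else "non-frail",
              x$cadence_hz, x$transfer_duration_s,
              if (x$uses_walking_aid) "yes" else "no"))
  invisible(x)
}

# internal builder for contiguous protocol scripts
script_builder <- function() {
  ev <- new.env(parent = emptyenv())
  ev$start <- numeric(); ev$end <- numeric()
  ev$label <- character(); ev$phase <- character()
  ev$t <- 0
  ev$add <- function(label, dur, phase) {
    if (dur <= 0) return(invisible(NULL))
    ev$start <- c(ev$start, ev$t)
    ev$end <- c(ev$end, ev$t + dur)
    ev$label <- c(ev$label, label)
    ev$phase <- c(ev$phase, phase)
    ev$t <- ev$t + dur
    invisible(NULL)
  }
  ev
}

as_protocol_script <- function(ev) {
  df <- data.frame(start_s = ev$start, end_s = ev$end, label = ev$label,
                   phase = ev$phase, stringsAsFactors = FALSE)
  class(df) <- c("protocol_script", "data.frame")
  df
}

#' Script the standardized mobility protocol
#'
#' Builds the fine-grained event sequence of the standardized in-home
#' assessment: standing still in front of the chair for five seconds,
#' sitting down, the Timed Up and Go test at slow / normal (three
#' repetitions) / fast pace, the Five Times Chair Rise, a single stand-up,
#' bending over to pick something up, lying down on a bed with a turn, an
#' optional floor lie, and a 10 m aided walk for subjects who use a cane or
#' walker in daily life.  Movement durations are scaled by the profile's
#' speed factor; short seated instruction rests separate the items, as
#' subjects were allowed to rest between exercises.
#'
#' @param profile a [make_profile()] result.
#' @return a `protocol_script`: a data frame of contiguous events
#'   (`start_s`, `end_s`, `label`, `phase`) starting at 0, with explicit
#'   `sit_to_stand` / `stand_to_sit` transfer events.
#' @export
script_standardized <- function(profile) {
  sf <- profile$speed_factor
  td <- profile$transfer_duration_s
  b <- script_builder()
  tug <- function(walk_dur, phase) {
    b$add("sit_to_stand", td, phase)
    b$add("walking", walk_dur, phase)       # out, turn (as walking), back
    b$add("stand_to_sit", td, phase)
    b$add("sitting", 6, phase)              # instruction rest
  }
  b$add("standing", 5, "stand_still")                      # item 1
  b$add("stand_to_sit", td, "sit_down")                    # item 2
  b$add("sitting", 8, "sit_down")
  tug(14 * sf, "tug_slow")                                 # item 3
  for (i in 1:3) tug(10 * sf, paste0("tug_normal_", i))    # item 4
  tug(7 * sf, "tug_fast")                                  # item 5
  for (i in 1:5) {                                         # item 6
    b$add("sit_to_stand", td, "chair_rise")
    b$add("standing", 1, "chair_rise")
    b$add("stand_to_sit", td, "chair_rise")
    if (i < 5) b$add("sitting", 1, "chair_rise")
  }
  b$add("sitting", 6, "chair_rise")
  b$add("sit_to_stand", td, "stand_up")                    # item 7
  b$add("standing", 3, "stand_up")
  b$add("standing", 4, "bend_pick")                        # item 8
  b$add("walking", 4 * sf, "bed_lie")                      # item 9
  b$add("lying", 20, "bed_lie")                            # back + turn on side
  b$add("sit_to_stand", td, "bed_lie")                     # sit up and rise
  b$add("standing", 2, "bed_lie")
  if (profile$floor_lie) {                                 # item 10 (optional)
    b$add("walking", 2 * sf, "floor_lie")
    b$add("lying", 15, "floor_lie")
    b$add("sit_to_stand", td, "floor_lie")
    b$add("standing", 2, "floor_lie")
  }
  if (profile$uses_walking_aid) {                          # item 11 (aid users)
    b$add("walking", 12 * sf, "aided_walk")
  }
  b$add("stand_to_sit", td, "end_rest")
  b$add("sitting", 8, "end_rest")
  as_protocol_script(b)
}

#' Script a free-movement session
#'
#' Generates a semi-Markov activity sequence over sitting, standing,
#' walking and short lying bouts, emulating 30 minutes of self-chosen
#' in-home activities.  Dwell times are markedly longer than in the
#' standardized protocol; every sitting-to-standing boundary carries an
#' explicit `sit_to_stand` event and every standing-to-sitting boundary a
#' `stand_to_sit` event.  The scripted time equals `duration_s` exactly
#' (the last event is truncated).
#'
#' @param profile a [make_profile()] result.
#' @param duration_s session length in seconds (>= 60; default 1800).
#' @param seed integer seed.
#' @return a `protocol_script`.
#' @export
script_free <- function(profile, duration_s = 1800, seed) {
  if (duration_s < 60) stop("duration_s must be at least 60 s")
  td <- profile$transfer_duration_s
  dwell <- function(mean_s, min_s) max(min_s, rgamma(1, shape = 4, scale = mean_s / 4))
  with_seed(seed, {
    b <- script_builder()
    state <- "sitting"
    b$add("sitting", dwell(90, 10), "free")
    while (b$t < duration_s) {
      nxt <- switch(state,
        sitting  = if (runif(1) < 0.85) "standing" else "lying",
        standing = if (runif(1) < 0.55) "walking" else "sitting",
        walking  = "standing",
        lying    = "sitting")
      if (state == "sitting" && nxt == "standing") b$add("sit_to_stand", td, "free")
      if (state == "standing" && nxt == "sitting") b$add("stand_to_sit", td, "free")
      d <- switch(nxt,
        sitting  = dwell(90, 10),
        standing = dwell(30, 4),
        walking  = dwell(if (profile$frail) 15 else 25, 6),
        lying    = dwell(40, 15))
      b$add(nxt, d, "free")
      state <- nxt
    }
    df <- as_protocol_script(b)
    df <- df[df$start_s < duration_s, , drop = FALSE]
    df$end_s[nrow(df)] <- duration_s
    df
  })
}

# centred running mean with shrinking edge windows
runmean <- function(x, k) {
  n <- length(x)
  h <- max(1L, floor(k / 2))
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1)
}

#' Synthesize a sensor recording from a protocol script
#'
#' Turns a scripted activity sequence into the paired signals of the hybrid
#' necklace sensor plus a ground-truth annotation track:
#' \itemize{
#'   \item acceleration (50 Hz): a gravity vector per posture (tilted
#'     beyond the lying threshold during lying, with smooth re-orientation),
#'     a cadence-locked train of step peaks during walking (alternate-step
#'     asymmetry for walking-aid users, lateral sway), the canonical
#'     biphasic transfer transient (negated for stand-to-sit) with a brief
#'     forward trunk lean, and additive white noise;
#'   \item pressure (25 Hz): a barometric baseline shifted by the necklace
#'     height of the current posture (seat-height drop when seated, larger
#'     drop when lying), ramped smoothly through each transfer, plus a slow
#'     drift and noise that scale with `noise_std_g`.
#' }
#' The annotation track collapses the script to the video-observation
#' vocabulary (sitting, standing, walking, lying): transfer seconds are
#' assigned to the destination posture.
#'
#' @param script a `protocol_script` from [script_standardized()] or
#'   [script_free()].
#' @param profile the [make_profile()] used to script it.
#' @param noise_std_g standard deviation of the accelerometer white noise in
#'   g (default 0.05); barometer noise and drift scale proportionally.
#' @param seed integer seed; the same seed reproduces the recording
#'   bit for bit.
#' @param config a [tol_config()] (sampling rates, altimetry constant).
#' @return a list with elements `recording` ([sensor_recording()]),
#'   `truth` ([annotation_track()] in video vocabulary) and `script`.
#' @export
synthesize <- function(script, profile, noise_std_g = 0.05, seed,
                       config = tol_config()) {
  stopifnot(inherits(script, "protocol_script"))
  ra <- config$accel_rate; rp <- config$pressure_rate
  dur <- max(script$end_s)
  na <- round(dur * ra); np <- round(dur * rp)
  ta <- (seq_len(na) - 1) / ra
  tp <- (seq_len(np) - 1) / rp
  lab_a <- script$label[findInterval(ta, script$start_s)]
  lab_p <- script$label[findInterval(tp, script$start_s)]

  with_seed(seed, {
    ## --- orientation -------------------------------------------------
    tilt_target <- ifelse(lab_a == "lying", profile$lying_tilt_deg, 0)
    tilt_deg <- runmean(tilt_target, round(1.5 * ra))
    # forward trunk lean during each transfer
    for (i in which(script$label %in% c("sit_to_stand", "stand_to_sit"))) {
      j <- which(ta >= script$start_s[i] & ta < script$end_s[i])
      if (length(j)) {
        u <- (ta[j] - script$start_s[i]) / (script$end_s[i] - script$start_s[i])
        tilt_deg[j] <- tilt_deg[j] + 20 * sin(pi * u)
      }
    }
    ## --- dynamic acceleration along gravity --------------------------
    dyn <- numeric(na)
    sway <- numeric(na)
    for (i in seq_len(nrow(script))) {
      lab <- script$label[i]
      s0 <- script$start_s[i]; s1 <- script$end_s[i]
      if (lab == "walking") {
        steps <- seq(s0 + 0.3, s1 - 0.1, by = 1 / profile$cadence_hz)
        w <- 0.3                       # loading-response bump width, s
        for (k in seq_along(steps)) {
          amp <- profile$step_peak_g *
            (1 + profile$aid_asymmetry * if (k %% 2 == 0) 1 else -1)
          j <- which(ta >= steps[k] & ta < steps[k] + w)
          if (length(j)) {
            dyn[j] <- dyn[j] + amp * 0.5 * (1 - cos(2 * pi * (ta[j] - steps[k]) / w))
          }
        }
        j <- which(ta >= s0 & ta < s1)
        sway[j] <- sway[j] +
          2 * profile$sway_std_g * sin(pi * profile$cadence_hz * ta[j])
      } else if (lab %in% c("sit_to_stand", "stand_to_sit")) {
        j <- which(ta >= s0 & ta < s1)
        if (length(j)) {
          u <- (ta[j] - s0) / (s1 - s0)
          shape <- sin(2 * pi * u) * (0.5 - 0.5 * cos(2 * pi * u))
          shape <- shape / max(abs(shape))
          dyn[j] <- dyn[j] +
            0.35 * shape * (if (lab == "sit_to_stand") 1 else -1)
        }
      }
    }
    th <- tilt_deg * pi / 180
    accel <- cbind(
      sin(th) * (1 + dyn) + sway + rnorm(na, 0, noise_std_g),
      rnorm(na, 0, noise_std_g),
      cos(th) * (1 + dyn) + rnorm(na, 0, noise_std_g)
    )
    accel <- pmin(pmax(accel, -4), 4)

    ## --- pressure ----------------------------------------------------
    height <- ifelse(lab_p == "sitting", -profile$seat_height_m,
                     ifelse(lab_p == "lying", -0.9, 0))
    for (i in which(script$label %in% c("sit_to_stand", "stand_to_sit"))) {
      j <- which(tp >= script$start_s[i] & tp < script$end_s[i])
      if (length(j)) {
        h0 <- if (script$label[i] == "sit_to_stand") -profile$seat_height_m else 0
        h1 <- if (script$label[i] == "sit_to_stand") 0 else -profile$seat_height_m
        u <- (tp[j] - script$start_s[i]) / (script$end_s[i] - script$start_s[i])
        height[j] <- h0 + (h1 - h0) * 0.5 * (1 - cos(pi * u))
      }
    }
    height <- runmean(height, round(1 * rp))   # soften lying steps
    drift <- cumsum(rnorm(np, 0, noise_std_g * 0.001))
    pressure <- 1013.25 - height / config$metres_per_hpa + drift +
      rnorm(np, 0, noise_std_g * 0.1)
  })

  rec <- sensor_recording(ta, accel, tp, pressure,
                          accel_rate = ra, pressure_rate = rp,
                          frail = profile$frail)
  list(recording = rec,
       truth = collapse_to_video_track(script),
       script = script)
}

#' Fine-grained ground-truth track from a protocol script
#'
#' The script's events (including explicit transfer events) as an
#' [annotation_track()] — the exact ground truth of a synthetic recording,
#' as opposed to the video-vocabulary collapse of
#' [collapse_to_video_track()].
#'
#' @param script a `protocol_script`.
#' @return an [annotation_track()].
#' @export
script_to_track <- function(script) {
  annotation_track(script$start_s, script$end_s, script$label)
}

#' Collapse a fine-grained script to the video annotation vocabulary
#'
#' Video observation scored only sitting, standing, walking and lying.
#' Transfer events are assigned to the destination posture (`sit_to_stand`
#' to standing, `stand_to_sit` to sitting) and adjacent same-label events
#' are merged.
#'
#' @param script a `protocol_script`.
#' @return an [annotation_track()] over the video vocabulary.
#' @export
collapse_to_video_track <- function(script) {
  lab <- script$label
  lab[lab == "sit_to_stand"] <- "standing"
  lab[lab == "stand_to_sit"] <- "sitting"
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  annotation_track(script$start_s[starts], script$end_s[ends], r$values)
}
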