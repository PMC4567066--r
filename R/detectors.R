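#' Detection intervals
#'
#' Output container of the per-modality detectors: sorted, non-overlapping
#' half-open intervals of one kind, with optional per-interval attributes
#' (e.g. `step_count` for walking bouts).
#'
#' @param kind one of `"active"`, `"sit_to_stand"`, `"stand_to_sit"`,
#'   `"walking"`, `"lying"`.
#' @param start_s,end_s numeric vectors of interval bounds (seconds).
#' @param ... additional per-interval attribute vectors (recycled rules of
#'   `data.frame`).
#' @return a `detection_intervals` data frame.
#' @export
detection_intervals <- function(kind, start_s = numeric(), end_s = numeric(),
                                ...) {
  kind <- match.arg(kind, c("active", "sit_to_stand", "stand_to_sit",
                            "walking", "lying"))
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   ..., stringsAsFactors = FALSE)
  if (nrow(df)) {
    o <- order(df$start_s)
    df <- df[o, , drop = FALSE]
    if (any(df$end_s <= df$start_s)) stop("empty or inverted interval")
    if (nrow(df) > 1L && any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9)) {
      stop("overlapping intervals within kind '", kind, "'")
    }
    rownames(df) <- NULL
  }
  structure(df, kind = kind, class = c("detection_intervals", "data.frame"))
}

# Maximal TRUE-runs of a logical sample mask, as intervals in seconds.
runs_to_intervals <- function(mask, rate, t0 = 0) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  cbind(start_s = t0 + starts[keep] / rate,
        end_s = t0 + ends[keep] / rate)
}

#' Detect active periods from the intensity signal
#'
#' Active and inactive periods are separated by an experimental intensity
#' threshold: maximal runs of samples with intensity at or above the
#' threshold become active bouts; gaps up to `merge_gap_s` between bouts are
#' merged, and bouts shorter than `min_bout_s` are dropped.  The complement
#' of the active intervals is inactive.
#'
#' @param intens intensity series (g), see [intensity()].
#' @param rate sampling rate of the intensity series (Hz).
#' @param threshold intensity threshold in g (> 0).
#' @param min_bout_s minimum bout duration (s).
#' @param merge_gap_s maximum sub-threshold gap merged into a bout (s).
#' @return [detection_intervals()] of kind `"active"`.
#' @export
detect_active <- function(intens, rate, threshold, min_bout_s = 1,
                          merge_gap_s = 2) {
  if (threshold <= 0) stop("threshold must be positive")
  iv <- runs_to_intervals(intens >= threshold, rate)
  if (nrow(iv) > 1L) {
    merged <- iv[1, , drop = FALSE]
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] - merged[nrow(merged), 2] <= merge_gap_s) {
        merged[nrow(merged), 2] <- iv[i, 2]
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
    iv <- merged
  }
  if (nrow(iv)) iv <- iv[iv[, 2] - iv[, 1] >= min_bout_s, , drop = FALSE]
  detection_intervals("active", iv[, 1], iv[, 2])
}

#' Detect walking bouts by repetitive step peaks
#'
#' Walking produces repetitive peaks in the norm of the tri-axial
#' acceleration.  Peaks above `min_peak_height_g` (after removal of the slow
#' gravity baseline) whose consecutive intervals fall inside the plausible
#' cadence range are grouped into bouts; a bout needs at least `min_peaks`
#' peaks (default 2 — walking is defined with a minimum of two steps).  Each
#' bout carries a `step_count` attribute.
#'
#' @param norm acceleration-norm series (g).
#' @param rate sampling rate (Hz).
#' @param min_peaks minimum number of step peaks per bout.
#' @param min_peak_height_g minimum peak height above baseline (g).
#' @param peak_interval_range_s admissible peak-to-peak interval, seconds.
#' @param baseline_cutoff_hz cut-off of the slow baseline removed before
#'   peak picking (default 0.25 Hz).
#' @return [detection_intervals()] of kind `"walking"` with a `step_count`
#'   column.
#' @export
detect_walking <- function(norm, rate, min_peaks = 2,
                           min_peak_height_g = 0.1,
                           peak_interval_range_s = c(0.35, 1.4),
                           baseline_cutoff_hz = 0.25) {
  stopifnot(min_peaks >= 1, min_peak_height_g > 0,
            all(peak_interval_range_s > 0))
  dev <- norm - lowpass(norm, rate, baseline_cutoff_hz)
  pk <- pracma::findpeaks(dev, minpeakheight = min_peak_height_g,
                          minpeakdistance = max(1L, round(peak_interval_range_s[1] * rate)))
  if (is.null(pk) || nrow(pk) == 0L) return(detection_intervals("walking"))
  pt <- sort(pk[, 2]) / rate            # peak times, seconds
  # split the peak sequence where the interval leaves the cadence range
  gaps <- diff(pt)
  grp <- cumsum(c(1, gaps < peak_interval_range_s[1] - 1e-9 |
                       gaps > peak_interval_range_s[2] + 1e-9))
  starts <- ends <- steps <- numeric(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < min_peaks) next
    step <- if (length(idx) > 1) median(diff(pt[idx])) else peak_interval_range_s[1]
    starts <- c(starts, max(0, pt[idx[1]] - step / 2))
    ends <- c(ends, pt[idx[length(idx)]] + step / 2)
    steps <- c(steps, length(idx))
  }
  # guard against touching bouts after the half-step extension
  if (length(starts) > 1L) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]; steps <- steps[o]
    for (i in 2:length(starts)) {
      if (starts[i] < ends[i - 1]) starts[i] <- ends[i - 1]
    }
  }
  detection_intervals("walking", starts, ends, step_count = steps)
}

#' Detect lying periods from sustained trunk tilt
#'
#' A sustained period with the upright body axis tilted beyond
#' `angle_threshold_deg` from gravity (i.e. the trunk close to horizontal)
#' is classified as lying, provided it lasts at least `min_duration_s`.
#'
#' @param tilt_deg tilt series in degrees, see [tilt()].
#' @param rate sampling rate (Hz).
#' @param angle_threshold_deg tilt threshold (default 60).
#' @param min_duration_s minimum sustained duration (default 10 s).
#' @return [detection_intervals()] of kind `"lying"`.
#' @export
detect_lying <- function(tilt_deg, rate, angle_threshold_deg = 60,
                         min_duration_s = 10) {
  stopifnot(angle_threshold_deg > 0, min_duration_s > 0)
  iv <- runs_to_intervals(as.numeric(tilt_deg) > angle_threshold_deg, rate)
  if (nrow(iv)) iv <- iv[iv[, 2] - iv[, 1] >= min_duration_s, , drop = FALSE]
  detection_intervals("lying", iv[, 1], iv[, 2])
}

#' Canonical sit-to-stand transfer template
#'
#' The biphasic acceleration-norm waveform of a sit-to-stand transfer: a
#' push-off peak followed by an unweighting valley, tapered to zero at both
#' ends.  A stand-to-sit transfer produces the negated waveform.  The same
#' canonical shape drives the synthetic generator's transfer model, so the
#' template is self-consistent with the test bench.
#'
#' @param rate sampling rate (Hz).
#' @param duration_s template duration (default 2.5 s).
#' @return unit-amplitude numeric vector with attributes `rate` and
#'   `version`.
#' @export
transfer_template <- function(rate = 50, duration_s = 2.5) {
  n <- round(duration_s * rate)
  t <- seq_len(n) / n                       # (0, 1]
  w <- sin(2 * pi * t) * (0.5 - 0.5 * cos(2 * pi * t))
  w <- w / max(abs(w))
  structure(w, rate = rate, version = "1.0")
}

#' Propose candidate transfer windows
#'
#' Sit/stand transfers appear as a transient in the low-passed acceleration
#' norm that coincides with a barometric altitude ramp (the necklace rises
#' or falls by roughly the seat height).  Candidates are runs of altitude
#' slope exceeding `transfer_slope_ms`, kept only when (i) the net altitude
#' change across the run exceeds `transfer_min_altitude_m` and (ii) a norm
#' transient above `transfer_norm_gate_g` occurs inside the window — the
#' gate rejects pure pressure drift without trunk acceleration.  Each
#' candidate carries a tight event interval (the supra-slope run) and a
#' wider centred feature window of `transfer_window_s` seconds.
#'
#' @param derived a [derive_signals()] result.
#' @param config a [tol_config()].
#' @return data frame with columns `centre_s`, `start_s`, `end_s`
#'   (event interval), `win_start_s`, `win_end_s` (feature window),
#'   `altitude_delta_m`.
#' @export
candidate_transfers <- function(derived, config = tol_config()) {
  alt <- derived$altitude_m
  rp <- derived$pressure_rate
  np <- length(alt)
  dur <- length(derived$norm_lp) / derived$accel_rate
  k <- max(1L, round(0.5 * rp))             # centred 1 s slope
  slope <- rep(0, np)
  idx <- (k + 1):(np - k)
  slope[idx] <- (alt[idx + k] - alt[idx - k]) / (2 * k / rp)
  iv <- runs_to_intervals(abs(slope) > config$transfer_slope_ms, rp)
  out <- data.frame(centre_s = numeric(), start_s = numeric(),
                    end_s = numeric(), win_start_s = numeric(),
                    win_end_s = numeric(), altitude_delta_m = numeric())
  if (!nrow(iv)) return(out)
  half <- config$transfer_window_s / 2
  for (i in seq_len(nrow(iv))) {
    # intensity before/after is unmeasurable at the recording edges
    if (iv[i, 1] < 0.5 || iv[i, 2] > dur - 0.5) next
    i0 <- max(1L, floor(iv[i, 1] * rp) + 1L)
    i1 <- min(np, ceiling(iv[i, 2] * rp))
    centre <- (i0 - 1L + which.max(abs(slope[i0:i1]))) / rp
    a0 <- alt[max(1L, round((iv[i, 1] - 0.25) * rp))]
    a1 <- alt[min(np, max(1L, round((iv[i, 2] + 0.25) * rp)))]
    if (abs(a1 - a0) < config$transfer_min_altitude_m) next
    if (abs(a1 - a0) > 2) next   # body-height change only; not an elevator
    # tight event interval: 10%-90% crossing of the altitude ramp (the raw
    # slope run is smeared by the centred difference and the low-pass)
    seg <- max(1L, round((iv[i, 1] - 0.5) * rp)):min(np, round((iv[i, 2] + 0.5) * rp))
    u <- (alt[seg] - a0) / (a1 - a0)
    in10 <- seg[u >= 0.1]; in90 <- seg[u <= 0.9]
    ev0 <- if (length(in10)) (in10[1] - 1L) / rp - 0.15 else iv[i, 1]
    ev1 <- if (length(in90)) (in90[length(in90)] - 1L) / rp + 0.15 else iv[i, 2]
    if (ev1 <= ev0) { ev0 <- iv[i, 1]; ev1 <- iv[i, 2] }
    # keep the full window width inside the recording (shift, don't clip)
    ws <- min(max(0, centre - half), max(0, dur - 2 * half))
    we <- min(dur, ws + 2 * half)
    j0 <- max(1L, floor(ws * derived$accel_rate) + 1L)
    j1 <- min(length(derived$norm_lp), ceiling(we * derived$accel_rate))
    if (max(abs(derived$norm_lp[j0:j1] - 1)) < config$transfer_norm_gate_g) next
    out <- rbind(out, data.frame(
      centre_s = centre,
      start_s = max(0, ev0),
      end_s = min(dur, ev1),
      win_start_s = ws, win_end_s = we,
      altitude_delta_m = a1 - a0))
  }
  out
}

#' Compute the transfer feature vector for a candidate window
#'
#' The five-feature set fed to the transfer classifier: peak normalized
#' cross-correlation with the canonical transfer template, time difference
#' between the signal peak and valley, sensor orientation at the transfer
#' midpoint, signal intensity before and after the transfer, and the
#' barometric altitude change across the candidate.
#'
#' @param window one row of [candidate_transfers()] output (a list or
#'   one-row data frame with `centre_s`, `start_s`, `end_s`, `win_start_s`,
#'   `win_end_s`).
#' @param derived a [derive_signals()] result.
#' @param template transfer template from [transfer_template()] at the
#'   acceleration rate.
#' @return a named numeric vector of class `transfer_features` with
#'   elements `template_xcorr`, `peak_valley_dt`, `orientation_deg`,
#'   `intensity_before`, `intensity_after`, `altitude_delta_m`.
#' @export
transfer_features <- function(window, derived,
                              template = transfer_template(derived$accel_rate)) {
  ra <- derived$accel_rate
  n <- length(derived$norm_lp)
  j0 <- max(1L, floor(window$win_start_s * ra) + 1L)
  j1 <- min(n, ceiling(window$win_end_s * ra))
  x <- derived$norm_lp[j0:j1] - 1
  if (length(x) < length(template)) {
    stop("feature error: candidate window shorter than the transfer template")
  }
  xc <- xcorr_peak(x, as.numeric(template))
  ipk <- which.max(x); ivl <- which.min(x)
  dt <- abs(ipk - ivl) / ra
  mid <- min(n, max(1L, round(window$centre_s * ra)))
  # intensity in the second before the event start / after the event end
  ib <- mean_in_window(derived$intensity, ra, window$start_s - 1, window$start_s)
  ia <- mean_in_window(derived$intensity, ra, window$end_s, window$end_s + 1)
  alt_delta <- window$altitude_delta_m %||% {
    rp <- derived$pressure_rate; np <- length(derived$altitude_m)
    derived$altitude_m[min(np, max(1L, round(window$end_s * rp)))] -
      derived$altitude_m[max(1L, round(window$start_s * rp))]
  }
  structure(
    c(template_xcorr = xc,
      peak_valley_dt = dt,
      orientation_deg = as.numeric(derived$tilt_deg[mid]),
      intensity_before = ib,
      intensity_after = ia,
      altitude_delta_m = as.numeric(alt_delta)),
    class = "transfer_features"
  )
}

# signed correlation at the lag of maximum |correlation| between the window
# and the template; 0 when either side is flat
xcorr_peak <- function(x, template) {
  nt <- length(template)
  if (sd(template) == 0) return(0)
  lags <- 0:(length(x) - nt)
  best <- 0
  for (l in lags) {
    seg <- x[(l + 1):(l + nt)]
    if (sd(seg) < 1e-12) next
    r <- cor(seg, template)
    if (abs(r) > abs(best)) best <- r
  }
  best
}

mean_in_window <- function(x, rate, t0, t1) {
  n <- length(x)
  i0 <- min(n, max(1L, floor(t0 * rate) + 1L))
  i1 <- min(n, max(i0, ceiling(t1 * rate)))
  mean(x[i0:i1])
}
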