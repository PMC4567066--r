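#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forwards and backwards
#' (filter-filter), so the filtered series is not delayed relative to the
#' raw one — essential when detector output is compared second-by-second
#' with annotations.
#'
#' @param x numeric vector, uniformly sampled.
#' @param rate sampling rate in Hz.
#' @param cutoff_hz cut-off frequency; must be below the Nyquist frequency
#'   `rate / 2`.
#' @param order Butterworth order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, rate, cutoff_hz, order = 4) {
  if (cutoff_hz >= rate / 2) {
    stop("parameter error: cutoff_hz (", cutoff_hz,
         ") must be below the Nyquist frequency ", rate / 2, " Hz")
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  # filter the mean-removed signal with odd-reflection padding: the
  # forward-backward pass zero-pads internally, which would otherwise
  # produce large start/end transients on signals with a big baseline
  # (e.g. barometric pressure around 1013 hPa)
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  p <- min(n - 1L, max(3L * order, ceiling(3 * rate / cutoff_hz)))
  xp <- c(2 * xc[1] - xc[(p + 1L):2L], xc, 2 * xc[n] - xc[(n - 1L):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1L):(p + n)] + mu
}

#' Euclidean norm of a tri-axial acceleration signal
#'
#' @param accel_xyz numeric matrix with three columns, in g.
#' @return numeric vector of per-sample norms (g).  A static device reads
#'   approximately 1 g in any orientation.
#' @export
accel_norm <- function(accel_xyz) {
  accel_xyz <- as.matrix(accel_xyz)
  stopifnot(ncol(accel_xyz) == 3L)
  sqrt(rowSums(accel_xyz^2))
}

#' Signal intensity (moving dispersion of dynamic acceleration)
#'
#' Intensity is the moving standard deviation of the acceleration norm over
#' a centred window.  Subtracting the window mean removes the (locally
#' constant) gravity component, so the statistic measures the dispersion of
#' the dynamic acceleration only: zero at rest, roughly `A / sqrt(2)` for a
#' sustained oscillation of amplitude `A`.
#'
#' @param norm acceleration-norm series (g).
#' @param rate sampling rate in Hz.
#' @param window_s window length in seconds (>= 0.5; default 1).
#' @return non-negative series of the same length (windows shrink at the
#'   edges).
#' @export
intensity <- function(norm, rate, window_s = 1) {
  if (window_s < 0.5) stop("window_s must be at least 0.5 s")
  n <- length(norm)
  h <- max(1L, round(window_s * rate / 2))
  cs <- cumsum(c(0, norm))
  cs2 <- cumsum(c(0, norm^2))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  m <- hi - lo + 1
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s^2 / m) / pmax(m - 1, 1)
  sqrt(pmax(v, 0))
}

#' Tilt of the body axis relative to gravity
#'
#' Angle in degrees between the configured upright axis of the sensor and
#' the measured gravity vector (the low-passed acceleration).  0 degrees is
#' fully upright, 90 degrees horizontal.  Samples whose gravity-vector
#' magnitude falls below 0.2 g (free fall, violent motion) carry no usable
#' orientation and are flagged unreliable.
#'
#' @param accel_xyz_lp low-passed tri-axial acceleration (gravity estimate),
#'   matrix with columns x, y, z.
#' @param upright_axis `"x"`, `"y"` or `"z"` (default `"z"`).
#' @return numeric vector of angles in `[0, 180]` with a logical attribute
#'   `unreliable`.
#' @export
tilt <- function(accel_xyz_lp, upright_axis = "z") {
  accel_xyz_lp <- as.matrix(accel_xyz_lp)
  ax <- match(match.arg(upright_axis, c("x", "y", "z")), c("x", "y", "z"))
  gmag <- sqrt(rowSums(accel_xyz_lp^2))
  unreliable <- gmag < 0.2
  cosang <- accel_xyz_lp[, ax] / pmax(gmag, .Machine$double.eps)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  structure(ang, unreliable = unreliable)
}

#' Relative altitude from barometric pressure
#'
#' Converts low-passed barometric pressure to altitude relative to the
#' start of the recording: `altitude[k] = -(p[k] - p[1]) * metres_per_hpa`.
#' Near sea level one hPa of pressure drop corresponds to about 8.43 m of
#' climb; the constant is configurable.
#'
#' @param pressure_lp low-passed pressure series (hPa).
#' @param metres_per_hpa altimetry constant (default 8.43 m/hPa).
#' @return altitude series in metres; the first sample is 0 by construction.
#' @export
relative_altitude <- function(pressure_lp, metres_per_hpa = 8.43) {
  -(pressure_lp - pressure_lp[1]) * metres_per_hpa
}

#' Derive all conditioned signals from a raw recording
#'
#' Runs the full signal-conditioning front end: detection-band and
#' gravity-band low-passes of the acceleration, the acceleration norm and
#' its intensity, trunk tilt, and pressure-derived relative altitude.
#' De-noised and smoothed signals are the input to each of the detection
#' modules.
#'
#' @param recording a [sensor_recording()].
#' @param config a [tol_config()].
#' @return A `derived_signals` list: `accel_lp` (detection band), `gravity`
#'   (gravity band), `norm` and `norm_lp`, `intensity`, `tilt_deg`,
#'   `altitude_m`, the two time grids and rates.
#' @export
derive_signals <- function(recording, config = tol_config()) {
  stopifnot(inherits(recording, "sensor_recording"))
  ra <- recording$accel_rate
  accel_lp <- apply(recording$accel_xyz, 2, lowpass, rate = ra,
                    cutoff_hz = config$cutoff_detect_hz,
                    order = config$filter_order)
  gravity <- apply(recording$accel_xyz, 2, lowpass, rate = ra,
                   cutoff_hz = config$cutoff_gravity_hz,
                   order = config$filter_order)
  nrm <- accel_norm(recording$accel_xyz)
  nrm_lp <- accel_norm(accel_lp)
  structure(
    list(
      accel_time = recording$accel_time,
      accel_rate = ra,
      accel_lp = accel_lp,
      gravity = gravity,
      norm = nrm,
      norm_lp = nrm_lp,
      intensity = intensity(nrm_lp, ra, config$intensity_window_s),
      tilt_deg = tilt(gravity, config$upright_axis),
      pressure_time = recording$pressure_time,
      pressure_rate = recording$pressure_rate,
      altitude_m = relative_altitude(
        lowpass(recording$pressure, recording$pressure_rate,
                config$cutoff_pressure_hz, config$filter_order),
        config$metres_per_hpa)
    ),
    class = "derived_signals"
  )
}
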