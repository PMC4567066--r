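#' Pipeline configuration
#'
#' All tunable parameters of the detection pipeline in one flat list.  The
#' source description of the method names the processing steps but not their
#' constants (filter type and cut-offs, the "experimental" activity
#' threshold, walking peak criteria, the lying angle); every such constant is
#' therefore surfaced here with a documented default rather than hidden in
#' code.
#'
#' @param ... named overrides of the defaults below.
#'
#' @details Defaults:
#' \describe{
#'   \item{accel_rate, pressure_rate}{sampling rates, Hz (50 and 25).}
#'   \item{cutoff_detect_hz}{low-pass cut-off for the detection signals
#'     (norm, walking peaks), Hz; default 5, the upper edge of voluntary
#'     human movement.}
#'   \item{cutoff_gravity_hz}{low-pass cut-off for the gravity/orientation
#'     estimate, Hz; default 0.25.}
#'   \item{cutoff_pressure_hz}{low-pass cut-off for the barometric signal,
#'     Hz; default 1.}
#'   \item{filter_order}{Butterworth order, default 4 (applied forwards and
#'     backwards, so the effective order is 8).}
#'   \item{intensity_window_s}{window of the moving standard deviation used
#'     as signal intensity, seconds; default 1.}
#'   \item{metres_per_hpa}{barometric altimetry constant, metres of altitude
#'     per hPa of pressure drop near sea level; default 8.43.}
#'   \item{upright_axis}{body axis aligned with gravity when upright; one of
#'     "x", "y", "z" (default "z").}
#'   \item{active_threshold_g}{intensity threshold separating active from
#'     inactive signal, g; default 0.04.}
#'   \item{active_min_bout_s, active_merge_gap_s}{minimum active bout length
#'     and maximum gap merged into a bout, seconds (1 and 2).}
#'   \item{walk_min_peaks}{minimum number of consecutive step peaks for a
#'     walking bout; default 2 (walking is defined with a minimum of two
#'     steps).}
#'   \item{walk_min_peak_height_g}{minimum step-peak height above the local
#'     gravity baseline, g; default 0.08 — below the weakest plausible
#'     cane-side step of a frail walker (about 0.12 g at the trunk) yet
#'     several standard deviations above the noise floor of the
#'     detection-band signal.}
#'   \item{walk_peak_interval_range_s}{admissible interval between
#'     consecutive step peaks, seconds; default c(0.35, 1.4), covering slow
#'     frail gait through brisk walking.}
#'   \item{lying_angle_threshold_deg, lying_min_duration_s}{tilt beyond which
#'     the trunk counts as horizontal (60 degrees) and the minimum sustained
#'     duration (10 s).}
#'   \item{transfer_window_s}{width of the feature window around a candidate
#'     transfer, seconds; default 3.5 (within the 2-6 s candidate range).}
#'   \item{transfer_slope_ms}{minimum absolute altitude slope marking a
#'     candidate transfer, m/s; default 0.08.}
#'   \item{transfer_min_altitude_m}{minimum absolute altitude change across a
#'     candidate window, metres; default 0.15.}
#'   \item{transfer_norm_gate_g}{minimum low-passed norm transient required
#'     inside a candidate window, g; default 0.05 (rejects pure pressure
#'     drift such as lying down without trunk acceleration).}
#'   \item{template_duration_s}{duration of the canonical transfer template,
#'     seconds; default 2.5.}
#'   \item{clock_offset_s}{offset added to annotation times to align video
#'     and sensor clocks; default 0 (a shared zero is assumed).}
#' }
#'
#' @return An object of class `tol_config` (a named list).
#' @examples
#' cfg <- tol_config(active_threshold_g = 0.05)
#' cfg$active_threshold_g
#' @export
tol_config <- function(...) {
  defaults <- list(
    accel_rate = 50,
    pressure_rate = 25,
    cutoff_detect_hz = 5,
    cutoff_gravity_hz = 0.25,
    cutoff_pressure_hz = 1,
    filter_order = 4,
    intensity_window_s = 1,
    metres_per_hpa = 8.43,
    upright_axis = "z",
    active_threshold_g = 0.04,
    active_min_bout_s = 1,
    active_merge_gap_s = 2,
    walk_min_peaks = 2,
    walk_min_peak_height_g = 0.08,
    walk_peak_interval_range_s = c(0.35, 1.4),
    lying_angle_threshold_deg = 60,
    lying_min_duration_s = 10,
    transfer_window_s = 3.5,
    transfer_slope_ms = 0.08,
    transfer_min_altitude_m = 0.15,
    transfer_norm_gate_g = 0.05,
    template_duration_s = 2.5,
    clock_offset_s = 0
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    }
    defaults <- modifyList(defaults, over)
  }
  structure(defaults, class = "tol_config")
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML so runs can be reproduced from a single
#' declarative file.
#'
#' @param path file path.
#' @param config a [tol_config()] object.
#' @return `read_tol_config()` returns a `tol_config`; `write_tol_config()`
#'   returns `path` invisibly.
#' @export
read_tol_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(tol_config, vals)
}

#' @rdname read_tol_config
#' @export
write_tol_config <- function(config, path) {
  stopifnot(inherits(config, "tol_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.tol_config <- function(x, ...) {
  cat("<tol_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
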