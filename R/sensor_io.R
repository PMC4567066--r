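#' Construct a sensor recording
#'
#' A `sensor_recording` pairs the two sample streams of the hybrid necklace
#' sensor: tri-axial acceleration (in g) and barometric pressure (in hPa),
#' each on its own uniform time grid.
#'
#' @param accel_time numeric vector, seconds from recording start.
#' @param accel_xyz numeric matrix with three columns (x, y, z), in g.
#' @param pressure_time numeric vector, seconds.
#' @param pressure numeric vector, hPa.
#' @param accel_rate,pressure_rate sampling rates in Hz (defaults 50 and 25).
#' @param subject_id optional subject identifier.
#' @param frail optional logical frailty flag.
#'
#' @details Invariants enforced: both time grids strictly increasing and
#'   uniformly spaced at the stated rate (tolerance 1e-6 s); all
#'   accelerations within the +/- 4 g sensor range; the two streams cover
#'   the same span to within one sample period.
#'
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(accel_time, accel_xyz, pressure_time, pressure,
                             accel_rate = 50, pressure_rate = 25,
                             subject_id = NA_character_, frail = NA) {
  accel_xyz <- as.matrix(accel_xyz)
  if (ncol(accel_xyz) != 3L) stop("accel_xyz must have three columns (x, y, z)")
  if (nrow(accel_xyz) != length(accel_time)) {
    stop("accel_time and accel_xyz lengths differ")
  }
  if (length(pressure) != length(pressure_time)) {
    stop("pressure_time and pressure lengths differ")
  }
  check_uniform_time(accel_time, accel_rate, "acceleration")
  check_uniform_time(pressure_time, pressure_rate, "pressure")
  if (max(abs(accel_xyz)) > 4 + 1e-9) {
    stop("acceleration outside the +/- 4 g sensor range")
  }
  span_a <- range(accel_time)
  span_p <- range(pressure_time)
  tol <- max(1 / accel_rate, 1 / pressure_rate) + 1e-9
  if (abs(span_a[1] - span_p[1]) > tol || abs(span_a[2] - span_p[2]) > tol) {
    stop("acceleration and pressure streams do not cover the same span ",
         "(difference exceeds one sample period)")
  }
  structure(
    list(accel_time = as.numeric(accel_time),
         accel_xyz = unname(accel_xyz),
         accel_rate = accel_rate,
         pressure_time = as.numeric(pressure_time),
         pressure = as.numeric(pressure),
         pressure_rate = pressure_rate,
         meta = list(subject_id = subject_id, frail = frail)),
    class = "sensor_recording"
  )
}

check_uniform_time <- function(tt, rate, what) {
  if (length(tt) < 2L) stop(what, " stream needs at least two samples")
  d <- diff(tt)
  if (any(d <= 0)) {
    stop(what, " time not strictly increasing at row ", which(d <= 0)[1] + 1L)
  }
  if (any(abs(d - 1 / rate) > 1e-6)) {
    bad <- which(abs(d - 1 / rate) > 1e-6)[1]
    stop(what, " time not uniformly spaced at 1/", rate, " s (row ",
         bad + 1L, ")")
  }
  invisible(TRUE)
}

#' Duration of a recording in seconds
#' @param recording a [sensor_recording()].
#' @return duration in seconds (number of acceleration samples divided by the
#'   sampling rate).
#' @export
recording_duration <- function(recording) {
  length(recording$accel_time) / recording$accel_rate
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %.1f s | accel %d Hz (%d samples) | pressure %d Hz (%d samples)\n",
              recording_duration(x), x$accel_rate, nrow(x$accel_xyz),
              x$pressure_rate, length(x$pressure)))
  if (!is.na(x$meta$subject_id)) {
    cat("  subject:", x$meta$subject_id,
        if (isTRUE(x$meta$frail)) "(frail)" else if (isFALSE(x$meta$frail)) "(non-frail)" else "",
        "\n")
  }
  invisible(x)
}

default_format_config <- function() {
  list(accel = c(time = "time_s", x = "ax_g", y = "ay_g", z = "az_g"),
       pressure = c(time = "time_s", pressure = "pressure_hpa"),
       accel_scale = 1, pressure_scale = 1, sep = "\t")
}

#' Read / write raw sensor files
#'
#' Recordings are exchanged as two delimited text files with headers: an
#' acceleration file (`time_s, ax_g, ay_g, az_g`) and a pressure file
#' (`time_s, pressure_hpa`).  A small column-mapping configuration supports
#' dialect variation (other column names, unit scale factors, separator).
#'
#' @param accel_path,pressure_path file paths.
#' @param format_config optional list overriding elements of the default
#'   mapping: `accel` and `pressure` named character vectors of column names,
#'   `accel_scale`/`pressure_scale` multiplicative factors converting stored
#'   units to g and hPa, and `sep`.
#' @param accel_rate,pressure_rate,subject_id,frail passed to
#'   [sensor_recording()].
#' @return `read_recording()` returns a [sensor_recording()];
#'   `write_recording()` returns the paths invisibly.
#' @export
read_recording <- function(accel_path, pressure_path, format_config = NULL,
                           accel_rate = 50, pressure_rate = 25,
                           subject_id = NA_character_, frail = NA) {
  fc <- modifyList(default_format_config(), format_config %||% list())
  acc <- read.table(accel_path, header = TRUE, sep = fc$sep,
                    stringsAsFactors = FALSE)
  prs <- read.table(pressure_path, header = TRUE, sep = fc$sep,
                    stringsAsFactors = FALSE)
  need_a <- fc$accel
  if (!all(need_a %in% names(acc))) {
    stop("format error: acceleration file missing column(s): ",
         paste(setdiff(need_a, names(acc)), collapse = ", "))
  }
  need_p <- fc$pressure
  if (!all(need_p %in% names(prs))) {
    stop("format error: pressure file missing column(s): ",
         paste(setdiff(need_p, names(prs)), collapse = ", "))
  }
  sensor_recording(
    accel_time = acc[[need_a[["time"]]]],
    accel_xyz = as.matrix(acc[, need_a[c("x", "y", "z")]]) * fc$accel_scale,
    pressure_time = prs[[need_p[["time"]]]],
    pressure = prs[[need_p[["pressure"]]]] * fc$pressure_scale,
    accel_rate = accel_rate, pressure_rate = pressure_rate,
    subject_id = subject_id, frail = frail
  )
}

#' @rdname read_recording
#' @param recording a [sensor_recording()].
#' @export
write_recording <- function(recording, accel_path, pressure_path) {
  stopifnot(inherits(recording, "sensor_recording"))
  acc <- data.frame(time_s = recording$accel_time,
                    ax_g = recording$accel_xyz[, 1],
                    ay_g = recording$accel_xyz[, 2],
                    az_g = recording$accel_xyz[, 3])
  prs <- data.frame(time_s = recording$pressure_time,
                    pressure_hpa = recording$pressure)
  write.table(format(acc, digits = 15, trim = TRUE, scientific = FALSE),
              accel_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(format(prs, digits = 15, trim = TRUE, scientific = FALSE),
              pressure_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(accel_path, pressure_path))
}

#' Construct an annotation track
#'
#' An annotation track is a sorted, non-overlapping list of labeled time
#' intervals (half-open, `[start_s, end_s)`), either ground-truth activity
#' annotations (as exported from video observation) or detector output.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param label character vector of activity labels.  Labels outside the
#'   vocabulary (sitting, standing, walking, lying, sit_to_stand,
#'   stand_to_sit, active, inactive, other) are mapped to `"other"` with a
#'   warning.
#' @return An `annotation_track`: a data frame with columns `start_s`,
#'   `end_s`, `label`, sorted by `start_s`.
#' @export
annotation_track <- function(start_s, end_s, label) {
  if (any(end_s <= start_s)) {
    bad <- which(end_s <= start_s)[1]
    stop("annotation error: event ", bad, " has end_s <= start_s")
  }
  label <- as.character(label)
  unknown <- !(label %in% ACTIVITY_LABELS)
  if (any(unknown)) {
    warning("unknown label(s) mapped to 'other': ",
            paste(unique(label[unknown]), collapse = ", "))
    label[unknown] <- "other"
  }
  o <- order(start_s)
  df <- data.frame(start_s = as.numeric(start_s)[o],
                   end_s = as.numeric(end_s)[o],
                   label = label[o], stringsAsFactors = FALSE)
  if (nrow(df) > 1L) {
    ov <- which(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9)
    if (length(ov)) {
      stop(sprintf("annotation error: events %d (%s [%.2f,%.2f)) and %d (%s [%.2f,%.2f)) overlap",
                   ov[1], df$label[ov[1]], df$start_s[ov[1]], df$end_s[ov[1]],
                   ov[1] + 1L, df$label[ov[1] + 1L], df$start_s[ov[1] + 1L],
                   df$end_s[ov[1] + 1L]))
    }
  }
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Read / write annotation event lists
#'
#' Annotation files are delimited text with a header and columns `start_s`,
#' `end_s`, `label` — the shape of a video-observation export.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param offset_s clock offset added to all event times, seconds (video
#'   and sensor clocks are assumed to share a zero; a known offset between
#'   them can be corrected here).
#' @return `read_annotations()` returns an [annotation_track()];
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path, sep = "\t", offset_s = 0) {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df))) {
    stop("format error: annotation file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  annotation_track(df$start_s + offset_s, df$end_s + offset_s, df$label)
}

#' @rdname read_annotations
#' @param track an [annotation_track()].
#' @export
write_annotations <- function(track, path, sep = "\t") {
  write.table(as.data.frame(track), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Per-second label series
#'
#' One activity label per whole second — the common currency of the fusion
#' classifier and the validation statistics.
#'
#' @param labels character vector, one entry per second.
#' @param origin_s integer second of the first entry.
#' @return A `second_labels` object (character vector with an `origin_s`
#'   attribute).
#' @export
second_labels <- function(labels, origin_s = 0L) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("a label series needs at least one second")
  ok <- labels %in% c(ACTIVITY_LABELS, "unlabeled")
  if (!all(ok)) {
    stop("label(s) outside vocabulary: ",
         paste(unique(labels[!ok]), collapse = ", "))
  }
  structure(labels, origin_s = as.integer(origin_s), class = "second_labels")
}

#' @export
print.second_labels <- function(x, ...) {
  r <- rle(as.vector(unclass(x)))
  cat(sprintf("<second_labels> %d s from t=%d\n", length(x), attr(x, "origin_s")))
  cat(paste(sprintf("%s x%d", r$values, r$lengths), collapse = " | "), "\n")
  invisible(x)
}

#' Convert interval annotations to a per-second label series
#'
#' Second `k` receives the label of the event covering the majority of
#' `[k, k+1)`.  Seconds not majority-covered by any event are `"unlabeled"`;
#' an exact 50/50 split between two events is resolved in favour of the
#' earlier-starting event.
#'
#' @param track an [annotation_track()].
#' @param span integer vector `c(t0, t1)`: the half-open second range
#'   `[t0, t1)` to label.
#' @return A [second_labels()] series of length `t1 - t0`.
#' @examples
#' tr <- annotation_track(c(0, 1.4), c(1.4, 3), c("sitting", "walking"))
#' events_to_seconds(tr, c(0, 3))
#' @export
events_to_seconds <- function(track, span) {
  stopifnot(length(span) == 2L, span[2] > span[1])
  t0 <- as.integer(span[1]); t1 <- as.integer(span[2])
  n <- t1 - t0
  out <- rep("unlabeled", n)
  if (nrow(track) > 0L) {
    for (k in seq_len(n)) {
      lo <- t0 + k - 1L; hi <- lo + 1L
      cov <- pmin(track$end_s, hi) - pmax(track$start_s, lo)
      hit <- which(cov > 1e-12)
      if (!length(hit)) next
      best <- max(cov[hit])
      if (best <= 0.5 - 1e-12) next          # no event holds a majority
      # ties go to the earlier-starting event (track is sorted by start)
      out[k] <- track$label[hit[which(cov[hit] >= best - 1e-12)][1]]
    }
  }
  second_labels(out, origin_s = t0)
}
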