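#' Assemble detector outputs onto a per-second label grid
#'
#' Each second of the recording carries every detector label whose
#' intervals cover the majority of that second (coverage of at least half
#' the second, summed over the detector's non-overlapping intervals).
#'
#' @param detections list of [detection_intervals()] (any subset of kinds).
#' @param duration_s recording duration in whole seconds.
#' @return a `label_grid`: logical matrix of `duration_s` rows and one
#'   column per kind (`sit_to_stand`, `stand_to_sit`, `walking`, `lying`,
#'   `active`).
#' @export
assemble <- function(detections, duration_s) {
  kinds <- c("sit_to_stand", "stand_to_sit", "walking", "lying", "active")
  n <- as.integer(duration_s)
  grid <- matrix(FALSE, nrow = n, ncol = length(kinds),
                 dimnames = list(NULL, kinds))
  for (det in detections) {
    kind <- attr(det, "kind")
    if (!nrow(det)) next
    if (any(det$start_s < -1e-9) || any(det$end_s > duration_s + 1e-9)) {
      stop("detection intervals outside [0, duration_s)")
    }
    for (k in seq_len(n)) {
      cov <- sum(pmax(0, pmin(det$end_s, k) - pmax(det$start_s, k - 1)))
      if (cov >= 0.5 - 1e-9) grid[k, kind] <- TRUE
    }
  }
  structure(grid, class = c("label_grid", class(grid)))
}

#' Resolve multi-label seconds by priority
#'
#' Seconds that received labels from several detection modules are
#' corrected following a descending priority of sit/stand transfers,
#' walking and lying (a second labeled both sit-to-stand and walking
#' becomes sit-to-stand).  Seconds carrying only the active flag stay
#' `"active"`; seconds with no label are `"inactive"` — both pending the
#' context rules.
#'
#' @param grid a [assemble()] result.
#' @return a [second_labels()] series.
#' @export
resolve <- function(grid) {
  n <- nrow(grid)
  out <- rep("inactive", n)
  out[grid[, "active"]] <- "active"
  out[grid[, "lying"]] <- "lying"
  out[grid[, "walking"]] <- "walking"
  out[grid[, "stand_to_sit"]] <- "stand_to_sit"
  out[grid[, "sit_to_stand"]] <- "sit_to_stand"
  second_labels(out)
}

#' Apply the sitting/standing context rules
#'
#' Each maximal run of active/inactive seconds is relabeled from its
#' flanking labels: to standing when it succeeds a sit-to-stand transfer or
#' walking and precedes a stand-to-sit transfer or walking; to sitting when
#' it succeeds a stand-to-sit transfer and precedes a sit-to-stand transfer
#' or lying.  Runs matching neither rule keep their active/inactive label
#' (un-labeled active periods still count towards time-on-legs).  A
#' recording boundary may stand in for one missing flank, but an entirely
#' unflanked run (both sides at the boundary) is never relabeled.
#'
#' @param labels a resolved [second_labels()] series.
#' @return a [second_labels()] series with context applied.
#' @export
context_rules <- function(labels) {
  x <- unclass(labels)
  n <- length(x)
  pending <- x %in% c("active", "inactive")
  r <- rle(pending)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    prev <- if (s > 1L) x[s - 1L] else "boundary"
    nxt <- if (e < n) x[e + 1L] else "boundary"
    if (prev == "boundary" && nxt == "boundary") next
    standing_ok <- (prev %in% c("sit_to_stand", "walking") || prev == "boundary") &&
                   (nxt %in% c("stand_to_sit", "walking") || nxt == "boundary")
    sitting_ok <- (prev == "stand_to_sit" || prev == "boundary") &&
                  (nxt %in% c("sit_to_stand", "lying") || nxt == "boundary")
    if (standing_ok) {
      x[s:e] <- "standing"
    } else if (sitting_ok) {
      x[s:e] <- "sitting"
    }
  }
  second_labels(x, origin_s = attr(labels, "origin_s"))
}

#' Compute time-on-legs from a label series
#'
#' Seconds classified as sit/stand transfers, walking, standing and the
#' remaining un-labeled active periods are categorized as time-on-legs
#' (ToL); sitting, lying and inactive seconds are not.
#'
#' @param labels a [second_labels()] series with context rules applied.
#' @return list with `tol_mask` (logical per second) and `tol_seconds`.
#' @export
compute_tol <- function(labels) {
  mask <- unclass(labels) %in% TOL_LABELS
  list(tol_mask = mask, tol_seconds = sum(mask))
}

#' Collapse sensor labels to the video vocabulary
#'
#' For category-wise comparison with video annotation (which scores only
#' sitting, standing, walking and lying), predicted transfer seconds are
#' assigned to the destination posture: `sit_to_stand` to standing,
#' `stand_to_sit` to sitting.
#'
#' @param labels a [second_labels()] series.
#' @return a [second_labels()] series over the video vocabulary (plus any
#'   residual active/inactive/unlabeled seconds).
#' @export
collapse_to_video <- function(labels) {
  x <- unclass(labels)
  x[x == "sit_to_stand"] <- "standing"
  x[x == "stand_to_sit"] <- "sitting"
  second_labels(x, origin_s = attr(labels, "origin_s"))
}
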