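#' Second-by-second sensitivity for one category
#'
#' Sensitivity is the total duration on which reference (video) and
#' prediction (sensor) correspond at the same moment for the category,
#' divided by the total duration the category was observed in the
#' reference, times 100.
#'
#' @param ref,pred equal-length label vectors (one label per second).
#' @param category the activity category.
#' @return percentage in `[0, 100]`, or `NA` ("not applicable") when the
#'   category never occurs in the reference — never 0, which would silently
#'   distort group means.
#' @export
sensitivity <- function(ref, pred, category) {
  check_pair(ref, pred)
  denom <- sum(ref == category)
  if (denom == 0) return(NA_real_)
  100 * sum(ref == category & pred == category) / denom
}

#' Second-by-second specificity for one category
#'
#' The total duration on which reference and prediction correspond for
#' non-category activity, divided by the total non-category duration in the
#' reference, times 100.
#'
#' @inheritParams sensitivity
#' @return percentage, or `NA` when the reference consists entirely of the
#'   category.
#' @export
specificity <- function(ref, pred, category) {
  check_pair(ref, pred)
  denom <- sum(ref != category)
  if (denom == 0) return(NA_real_)
  100 * sum(ref != category & pred != category) / denom
}

#' Overall second-by-second agreement across all categories
#'
#' The total duration on which reference and prediction carry the same
#' label, divided by the total observed duration, times 100.  Symmetric in
#' its arguments.
#'
#' @inheritParams sensitivity
#' @return percentage in `[0, 100]`.
#' @export
overall_agreement <- function(ref, pred) {
  check_pair(ref, pred)
  100 * sum(ref == pred) / length(ref)
}

check_pair <- function(ref, pred) {
  if (length(ref) != length(pred)) {
    stop("reference and prediction series differ in length (",
         length(ref), " vs ", length(pred), ")")
  }
  if (length(ref) < 1L) stop("empty label series")
  invisible(TRUE)
}

#' Reduce a label series to the binary time-on-legs signal
#'
#' Applies the same membership rule as [compute_tol()]: standing, walking,
#' sit/stand transfers and un-labeled active seconds are ToL; sitting,
#' lying, inactive and unlabeled seconds are not.
#'
#' @param labels a label vector.
#' @return character vector of `"tol"` / `"non_tol"`.
#' @export
to_tol_series <- function(labels) {
  ifelse(unclass(labels) %in% TOL_LABELS, "tol", "non_tol")
}

#' ToL-based sensitivity, specificity and overall agreement
#'
#' Reduces both series to the binary time-on-legs signal with
#' [to_tol_series()] and applies the three second-by-second metrics.
#'
#' @param ref reference labels (vector) or an [annotation_track()], which is
#'   converted with [events_to_seconds()] over the prediction's span.
#' @param pred predicted label vector.
#' @return named list `sensitivity`, `specificity`, `agreement` (percent).
#' @export
tol_metrics <- function(ref, pred) {
  if (inherits(ref, "annotation_track")) {
    ref <- events_to_seconds(ref, c(0, length(pred)))
  }
  r <- to_tol_series(ref); p <- to_tol_series(pred)
  list(sensitivity = sensitivity(r, p, "tol"),
       specificity = specificity(r, p, "tol"),
       agreement = overall_agreement(r, p))
}

#' Qualitative grade of an agreement percentage
#'
#' Fleiss-style cut-offs: at most 40% insufficient, above 40 up to 60%
#' moderate, above 60 up to 80% good, above 80% excellent.  Boundaries are
#' right-closed (40 is insufficient, 60 moderate, 80 good).
#'
#' @param percent value(s) in `[0, 100]`; `NA` passes through.
#' @return character vector of grades.
#' @export
grade <- function(percent) {
  if (any(percent < 0 | percent > 100, na.rm = TRUE)) {
    stop("parameter error: percentage outside [0, 100]")
  }
  as.character(cut(percent, breaks = c(-Inf, 40, 60, 80, Inf),
                   labels = c("insufficient", "moderate", "good", "excellent"),
                   right = TRUE))
}

#' Intraclass correlation, two-way random effects, average measures
#'
#' ICC(2,k) computed from the ANOVA mean squares of an `n x k` rating
#' matrix (n targets rated by the same k random raters).  The default
#' absolute-agreement form is
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)`; the consistency form
#' `(MSR - MSE) / MSR` is available by option.  Inter-rater reliability is
#' conventionally deemed sufficient above 0.8.
#'
#' @param mat numeric matrix, `n >= 2` targets by `k >= 2` raters, no
#'   missing cells.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param threshold pass threshold (default 0.8).
#' @return list with `value`, `pass` (`value > threshold`), `type`, and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_2k <- function(mat, type = c("agreement", "consistency"), threshold = 0.8) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters")
  if (anyNA(mat)) stop("rating matrix has missing cells")
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps && mse <= .Machine$double.eps) {
    stop("degenerate input: zero between-target variance")
  }
  value <- if (type == "agreement") {
    (msr - mse) / (msr + (msc - mse) / n)
  } else {
    (msr - mse) / msr
  }
  list(value = value, pass = value > threshold, type = type,
       msr = msr, msc = msc, mse = mse)
}

#' Compare sensor performance between frail and non-frail groups
#'
#' Independent-samples t-test on per-subject metric values; the
#' unequal-variance (Welch) form is the default, the pooled-variance form
#' is available by flag.  Degenerate cases (identical constant groups) are
#' reported as t = 0, p = 1 rather than an error.
#'
#' @param values_frail,values_nonfrail numeric vectors of per-subject
#'   values (each of length >= 2).
#' @param var_equal use the pooled-variance form?  Default `FALSE`.
#' @return list with `t`, `p`, `df`, `mean_frail`, `mean_nonfrail`; all
#'   `NA` when a group has fewer than two values.
#' @export
group_compare <- function(values_frail, values_nonfrail, var_equal = FALSE) {
  values_frail <- values_frail[!is.na(values_frail)]
  values_nonfrail <- values_nonfrail[!is.na(values_nonfrail)]
  if (length(values_frail) < 2 || length(values_nonfrail) < 2) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean_frail = mean(values_frail),
                mean_nonfrail = mean(values_nonfrail)))
  }
  if (sd(values_frail) == 0 && sd(values_nonfrail) == 0) {
    same <- mean(values_frail) == mean(values_nonfrail)
    return(list(t = if (same) 0 else Inf * sign(mean(values_frail) - mean(values_nonfrail)),
                p = if (same) 1 else 0,
                df = length(values_frail) + length(values_nonfrail) - 2,
                mean_frail = mean(values_frail),
                mean_nonfrail = mean(values_nonfrail)))
  }
  tt <- t.test(values_frail, values_nonfrail, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_frail = mean(values_frail), mean_nonfrail = mean(values_nonfrail))
}

#' Validation report against annotated ground truth
#'
#' Computes the full second-by-second validation table: one row for the
#' binary time-on-legs signal and one per activity category (sitting,
#' standing, walking, lying), with sensitivity, specificity and overall
#' agreement plus their qualitative grades.  Per-category agreement is the
#' binary (category vs non-category) agreement; the multi-category overall
#' agreement is reported alongside.  With several subjects the metrics are
#' computed group-wise on the concatenated series; per-subject values are
#' kept for the frail vs non-frail t-test when a frailty flag is supplied.
#' For the category rows both series are collapsed to the video vocabulary
#' ([collapse_to_video()]: transfer seconds go to their destination
#' posture); the ToL row uses the uncollapsed series, since transfer
#' seconds count as time-on-legs on both sides.  Passing the fine-grained
#' truth (with transfer labels) as `refs` therefore scores ToL exactly;
#' passing a video-vocabulary track reproduces the stricter comparison
#' against 4-category annotation.
#'
#' @param refs reference labels: a vector, an [annotation_track()], or a
#'   list of either (one per subject).
#' @param preds predicted labels: a vector or list matching `refs`.
#' @param frail optional logical vector, one flag per subject.
#' @param categories categories to report (default the video vocabulary).
#' @return a `validation_report`: list with `table` (the report data
#'   frame), `overall_agreement`, per-subject values, and — when `frail`
#'   is given — per-group tables and `group_tests`.
#' @export
validation_report <- function(refs, preds, frail = NULL,
                              categories = c("sitting", "standing",
                                             "walking", "lying")) {
  wrap <- function(x) {
    if (inherits(x, "annotation_track") || !is.list(x)) list(x) else x
  }
  refs <- wrap(refs)
  preds <- wrap(preds)
  stopifnot(length(refs) == length(preds))
  as_chr <- function(x) as.vector(unclass(x))
  norm_ref <- function(r, p) {
    if (inherits(r, "annotation_track")) r <- events_to_seconds(r, c(0, length(p)))
    as_chr(r)
  }
  preds_raw <- lapply(preds, as_chr)
  refs_raw <- mapply(norm_ref, refs, preds_raw, SIMPLIFY = FALSE)
  tovid <- function(x) as_chr(collapse_to_video(second_labels(x)))
  preds_v <- lapply(preds_raw, tovid)
  refs_v <- lapply(refs_raw, tovid)

  metric_rows <- function(idx) {
    ref <- unlist(refs_v[idx]); pred <- unlist(preds_v[idx])
    # ToL metrics use the uncollapsed series: transfer seconds are
    # time-on-legs on both sides
    tolm <- tol_metrics(unlist(refs_raw[idx]), unlist(preds_raw[idx]))
    rows <- data.frame(
      category = "TOL",
      sensitivity = tolm$sensitivity,
      specificity = tolm$specificity,
      agreement = tolm$agreement,
      stringsAsFactors = FALSE
    )
    for (cat in categories) {
      bin_ref <- ifelse(ref == cat, cat, "other")
      bin_pred <- ifelse(pred == cat, cat, "other")
      rows <- rbind(rows, data.frame(
        category = cat,
        sensitivity = sensitivity(ref, pred, cat),
        specificity = specificity(ref, pred, cat),
        agreement = overall_agreement(bin_ref, bin_pred),
        stringsAsFactors = FALSE))
    }
    rows
  }
  tab <- metric_rows(seq_along(refs_v))
  tab$sensitivity_grade <- grade(tab$sensitivity)
  tab$specificity_grade <- grade(tab$specificity)
  tab$agreement_grade <- grade(tab$agreement)

  per_subject <- lapply(seq_along(refs_v), function(i) metric_rows(i))

  out <- list(table = tab,
              overall_agreement = overall_agreement(unlist(refs_v),
                                                    unlist(preds_v)),
              per_subject = per_subject,
              n_subjects = length(refs_v),
              icc_type = "agreement")
  if (!is.null(frail) && any(frail) && any(!frail)) {
    out$table_frail <- metric_rows(which(frail))
    out$table_nonfrail <- metric_rows(which(!frail))
    pick <- function(i, row, col) per_subject[[i]][row, col]
    tests <- list()
    for (r in seq_len(nrow(tab))) {
      for (m in c("sensitivity", "specificity", "agreement")) {
        vf <- vapply(which(frail), pick, numeric(1), row = r, col = m)
        vn <- vapply(which(!frail), pick, numeric(1), row = r, col = m)
        tests[[paste(tab$category[r], m, sep = "_")]] <- group_compare(vf, vn)
      }
    }
    out$group_tests <- tests
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, digits = 1, ...) {
  cat(sprintf("<validation_report> %d subject(s) | overall agreement %.1f%%\n",
              x$n_subjects, x$overall_agreement))
  tab <- x$table
  cat(sprintf("  %-9s %12s %12s %12s\n", "", "Sensitivity", "Specificity",
              "Agreement"))
  for (i in seq_len(nrow(tab))) {
    fmt <- function(v, g) {
      if (is.na(v)) "n/a" else sprintf("%.*f (%s)", digits, v, g)
    }
    cat(sprintf("  %-9s %16s %16s %16s\n", tab$category[i],
                fmt(tab$sensitivity[i], tab$sensitivity_grade[i]),
                fmt(tab$specificity[i], tab$specificity_grade[i]),
                fmt(tab$agreement[i], tab$agreement_grade[i])))
  }
  if (!is.null(x$group_tests)) {
    ps <- vapply(x$group_tests, function(t) t$p, numeric(1))
    ps <- ps[!is.na(ps)]
    if (length(ps)) {
      cat(sprintf("  frail vs non-frail: min p = %.3f across %d tests\n",
                  min(ps), length(ps)))
    }
  }
  invisible(x)
}

#' Session totals
#'
#' Summarizes collected validation data the way study totals are reported:
#' total seconds, total hours, and mean duration per subject.
#'
#' @param seconds_per_subject numeric vector of per-subject durations (s).
#' @return list with `total_seconds`, `total_hours`, `mean_seconds`.
#' @examples
#' # 20 subjects totalling 11285 s -> 3.13 h, mean 564.25 s
#' session_totals(rep(11285 / 20, 20))
#' @export
session_totals <- function(seconds_per_subject) {
  list(total_seconds = sum(seconds_per_subject),
       total_hours = sum(seconds_per_subject) / 3600,
       mean_seconds = mean(seconds_per_subject))
}
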