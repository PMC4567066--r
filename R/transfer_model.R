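#' Build a labeled transfer-feature training set
#'
#' Synthesizes short labeled snippets — isolated sit-to-stand and
#' stand-to-sit transfers, quiet sitting, and walking — across frail and
#' non-frail profiles and several noise levels, runs the signal front end
#' and [transfer_features()] on each, and returns the measured feature
#' vectors with their class labels.  Because the features are measured from
#' synthesized signal (not drawn from a parametric cartoon), the training
#' distribution matches what the detector sees at run time.
#'
#' @param n_per_class snippets per class (default 60).
#' @param seed integer seed; the set is reproducible.
#' @param config a [tol_config()].
#' @return data frame with a factor `label` (sit_to_stand, stand_to_sit,
#'   none) and the six feature columns.
#' @export
make_transfer_training_set <- function(n_per_class = 60, seed = 20150911,
                                       config = tol_config()) {
  rows <- list()
  sub_seed <- function(i, j) (seed %% 100000L) * 10000L + i * 10L + j
  noises <- c(0.01, 0.03, 0.05)
  for (i in seq_len(n_per_class)) {
    frail <- i %% 2 == 0
    noise <- noises[1 + (i %% length(noises))]
    prof <- make_profile(frail, sub_seed(i, 1))
    td <- prof$transfer_duration_s

    snip <- function(labels, durs, take_centre, cls, j) {
      b <- script_builder()
      for (k in seq_along(labels)) b$add(labels[k], durs[k], "snippet")
      sc <- as_protocol_script(b)
      syn <- synthesize(sc, prof, noise_std_g = noise, seed = sub_seed(i, j),
                        config = config)
      der <- derive_signals(syn$recording, config)
      cands <- candidate_transfers(der, config)
      near <- if (nrow(cands)) which.min(abs(cands$centre_s - take_centre)) else integer(0)
      use_cand <- length(near) == 1L &&
        abs(cands$centre_s[near] - take_centre) < 2
      if (cls != "none" && !use_cand) return(NULL)  # missed transfer: skip, do not fake
      win <- if (use_cand) {
        as.list(cands[near, ])
      } else {
        half <- config$transfer_window_s / 2
        list(centre_s = take_centre,
             start_s = take_centre - 1, end_s = take_centre + 1,
             win_start_s = take_centre - half, win_end_s = take_centre + half,
             altitude_delta_m = NULL)
      }
      fe <- transfer_features(win, der,
                              transfer_template(config$accel_rate,
                                                config$template_duration_s))
      c(list(label = cls), as.list(unclass(fe)))
    }

    # vary the movement context so transfers embedded in walking (timed
    # up-and-go) and rises from lying (bed, floor) are in-distribution
    sts_ctx <- switch(1 + (i %% 3),
      list(c("sitting", "sit_to_stand", "standing"), c(4, td, 4), 4 + td / 2),
      list(c("sitting", "sit_to_stand", "walking"), c(4, td, 5), 4 + td / 2),
      list(c("walking", "lying", "sit_to_stand", "standing"), c(3, 12, td, 4),
           15 + td / 2))
    stn_ctx <- switch(1 + (i %% 2),
      list(c("standing", "stand_to_sit", "sitting"), c(4, td, 4), 4 + td / 2),
      list(c("walking", "stand_to_sit", "sitting"), c(5, td, 4), 5 + td / 2))
    none_ctx <- switch(1 + (i %% 5),
      list("sitting", 10, 5),                               # quiet rest
      list(c("standing", "walking", "standing"), c(2, 6, 2), 5),
      list(c("standing", "walking", "lying"), c(2, 3, 12), 5.5),  # lie-down
      list(c("sitting", "lying", "sitting"), c(4, 15, 6), 4),     # recline
      list(c("sitting", "lying", "sitting"), c(4, 15, 6), 19))    # sit up
    rows <- c(rows, list(
      snip(sts_ctx[[1]], sts_ctx[[2]], sts_ctx[[3]], "sit_to_stand", 2),
      snip(stn_ctx[[1]], stn_ctx[[2]], stn_ctx[[3]], "stand_to_sit", 3),
      snip(none_ctx[[1]], none_ctx[[2]], none_ctx[[3]], "none", 4)
    ))
  }
  rows <- Filter(Negate(is.null), rows)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df$label <- factor(df$label, levels = c("sit_to_stand", "stand_to_sit", "none"))
  rownames(df) <- NULL
  df
}

#' Train the sit/stand transfer classifier
#'
#' Fits a linear-kernel support vector machine to the five-feature transfer
#' vectors (template cross-correlation, peak-valley time difference,
#' orientation, intensity before/after, altitude change) on a synthetic
#' labeled training set, deciding between sit-to-stand, stand-to-sit and
#' rejection ("none").  Training data and seed are recorded on the model.
#'
#' @param n_per_class training snippets per class (default 60).
#' @param seed integer seed.
#' @param config a [tol_config()].
#' @return a `transfer_svm` object.
#' @seealso [transfer_threshold_model()] for the deterministic fallback.
#' @export
train_transfer_classifier <- function(n_per_class = 60, seed = 20150911,
                                      config = tol_config()) {
  df <- make_transfer_training_set(n_per_class, seed, config)
  fit <- e1071::svm(label ~ ., data = df, kernel = "linear", cost = 1,
                    scale = TRUE)
  structure(list(fit = fit, version = "1.0", seed = seed, n = nrow(df),
                 classes = levels(df$label)),
            class = "transfer_svm")
}

#' @export
print.transfer_svm <- function(x, ...) {
  cat(sprintf("<transfer_svm> v%s | linear kernel | %d training features | seed %d\n",
              x$version, x$n, x$seed))
  invisible(x)
}

#' @export
predict.transfer_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "transfer_features")) {
    newdata <- as.data.frame(as.list(unclass(newdata)))
  }
  as.character(predict(object$fit, newdata))
}

#' Deterministic threshold fallback for transfer classification
#'
#' A transparent alternative to the SVM: a candidate whose template
#' cross-correlation magnitude and altitude change both clear their
#' thresholds is labeled by the sign of the altitude change (rise =
#' sit-to-stand, drop = stand-to-sit); anything else is rejected.
#'
#' @param min_xcorr minimum `|template_xcorr|` (default 0.3).
#' @param min_altitude_m minimum `|altitude_delta_m|` (default 0.1).
#' @return a `transfer_threshold` model object.
#' @export
transfer_threshold_model <- function(min_xcorr = 0.3, min_altitude_m = 0.1) {
  structure(list(min_xcorr = min_xcorr, min_altitude_m = min_altitude_m,
                 version = "1.0"),
            class = "transfer_threshold")
}

#' Classify a candidate transfer
#'
#' Applies a trained margin classifier (or the deterministic threshold
#' fallback) to one [transfer_features()] vector.
#'
#' @param features a `transfer_features` vector.
#' @param model a `transfer_svm` or `transfer_threshold` model.
#' @return `"sit_to_stand"`, `"stand_to_sit"` or `"none"`.
#' @export
classify_transfer <- function(features, model) {
  if (is.null(model)) {
    stop("state error: transfer classifier has not been trained ",
         "(see train_transfer_classifier())")
  }
  if (inherits(model, "transfer_threshold")) {
    if (abs(features[["template_xcorr"]]) < model$min_xcorr ||
        abs(features[["altitude_delta_m"]]) < model$min_altitude_m) {
      return("none")
    }
    return(if (features[["altitude_delta_m"]] > 0) "sit_to_stand" else "stand_to_sit")
  }
  if (inherits(model, "transfer_svm")) {
    return(predict(model, features))
  }
  stop("unknown transfer model class: ", paste(class(model), collapse = "/"))
}

# session-cached default model (deterministic: fixed training seed)
default_transfer_model <- function(config = tol_config()) {
  if (is.null(.tolsense$transfer_model)) {
    .tolsense$transfer_model <- train_transfer_classifier(config = config)
  }
  .tolsense$transfer_model
}
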