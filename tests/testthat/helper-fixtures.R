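# Shared fixture builders.  Everything is generated in code; no data files.

# A quiet recording: device upright, constant gravity on z, flat pressure.
quiet_recording <- function(duration_s = 20, accel_rate = 50,
                            pressure_rate = 25) {
  na <- duration_s * accel_rate
  np <- duration_s * pressure_rate
  sensor_recording(
    accel_time = (seq_len(na) - 1) / accel_rate,
    accel_xyz = cbind(rep(0, na), rep(0, na), rep(1, na)),
    pressure_time = (seq_len(np) - 1) / pressure_rate,
    pressure = rep(1013.25, np)
  )
}

# One subject's zero-noise standardized run, classified with the given model.
standardized_run <- function(seed, frail = FALSE, noise = 0,
                             model = transfer_threshold_model()) {
  prof <- make_profile(frail, seed)
  sc <- script_standardized(prof)
  syn <- synthesize(sc, prof, noise_std_g = noise, seed = seed)
  cls <- classify_recording(syn$recording, model = model)
  list(profile = prof, script = sc, syn = syn, cls = cls,
       ref = events_to_seconds(script_to_track(sc), c(0, cls$duration_s)))
}

# The SVM is deterministic (fixed training seed); train it once per run.
cached_svm <- local({
  model <- NULL
  function() {
    if (is.null(model)) model <<- train_transfer_classifier()
    model
  }
})

label_chr <- function(x) as.vector(unclass(x))
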