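# The full-scale synthetic experiment shared by the end-to-end tests:
# a 12-subject cohort of 6-minute walks at 15 Hz (cadence 1.6-2.2 steps/s,
# left/right asymmetry 0.6-0.8, 0.05 g noise), a general CNN trained on the
# ENMO feature of 10 subjects with 2 held out, and its evaluation on every
# cohort subject. Trained once and cached for the session; three epochs are
# ample for this separable cohort (validation accuracy plateaus in one).

.experiment_cache <- new.env(parent = emptyenv())

general_model_experiment <- function() {
  if (!exists("res", envir = .experiment_cache)) {
    seed <- 1L
    cohort <- simulate_cohort(12, seed = seed, duration = 360,
                              sampling_rate = 15, noise_sd = 0.05)
    ds <- lapply(cohort, function(s) make_windows(s$recording, "ENMO1", 60))
    sp <- split_subjects(names(ds), n_val = 2, seed = seed)
    tcfg <- train_config(batch_size = 256, max_epochs = 3, patience = 3,
                         seed = seed)
    mdl <- train_model(build_model(model_config("CNN", "ENMO1"), seed),
                       bind_windows(ds[sp$train]), bind_windows(ds[sp$val]),
                       tcfg)
    per_subject <- lapply(cohort, function(s)
      predict_step_count(mdl, s$recording))
    assign("res",
           list(seed = seed, cohort = cohort, split = sp, model = mdl,
                per_subject = per_subject,
                count_acc = vapply(per_subject, `[[`, numeric(1),
                                   "step_count_accuracy"),
                class_acc = vapply(per_subject, `[[`, numeric(1),
                                   "step_classification_accuracy")),
           envir = .experiment_cache)
  }
  get("res", envir = .experiment_cache)
}

# A subject the general model was never trained for: cadence shifted +40%
# from the cohort midpoint (1.9 -> 2.66 steps/s, outside the 1.6-2.2
# training range) and the sensor's axes permuted (a differently mounted
# device).
make_outlier_subject <- function(seed = 2001L) {
  sim <- simulate_subject(gait_params(
    cadence = 1.9 * 1.4, duration = 360, sampling_rate = 15,
    noise_sd = 0.05, lr_asymmetry = 0.7, subject_id = "OUT01",
    device_id = "rotated", seed = seed))
  rec <- sim$recording$recording
  permuted <- accel_recording(rec$samples[, c(3, 1, 2)], rec$sampling_rate,
                              rec$subject_id, rec$device_id)
  list(recording = labeled_recording(permuted, sim$recording$labels),
       true_step_count = sim$true_step_count)
}
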