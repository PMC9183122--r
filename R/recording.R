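#' Construct a uniformly sampled tri-axial accelerometer recording
#'
#' An `accel_recording` holds an ordered sequence of (ax, ay, az) samples in
#' units of g, recorded at a uniform rate. Timestamps are session-relative
#' seconds: sample `i` is at `t0 + (i - 1) / sampling_rate`.
#'
#' @param samples numeric matrix with 3 columns (ax, ay, az) in g.
#' @param sampling_rate sampling rate in Hz (positive).
#' @param subject_id,device_id provenance identifiers.
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `accel_recording` with fields `samples`,
#'   `sampling_rate`, `subject_id`, `device_id`, `t0`.
#' @examples
#' rec <- accel_recording(matrix(c(0, 0, 1), 10, 3, byrow = TRUE), 15)
#' rec_duration(rec)
#' @export
accel_recording <- function(samples, sampling_rate, subject_id = "unknown",
                            device_id = "unknown", t0 = 0) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop("`samples` must have exactly 3 columns (ax, ay, az)")
  if (nrow(samples) < 1L)
    stop("recording must contain at least one sample")
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples)))
    stop("all acceleration values must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number")
  colnames(samples) <- c("ax", "ay", "az")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         subject_id = as.character(subject_id),
         device_id = as.character(device_id), t0 = as.numeric(t0)),
    class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf(
    "<accel_recording> subject=%s device=%s: %d samples at %g Hz (%.2f s)\n",
    x$subject_id, x$device_id, nrow(x$samples), x$sampling_rate,
    rec_duration(x)))
  invisible(x)
}

#' Recording sample times and duration
#'
#' @param rec an `accel_recording`.
#' @return `rec_times()`: vector of per-sample timestamps in seconds;
#'   `rec_duration()`: the time spanned, `(n - 1) / sampling_rate`.
#' @export
rec_times <- function(rec) {
  rec$t0 + (seq_len(nrow(rec$samples)) - 1) / rec$sampling_rate
}

#' @rdname rec_times
#' @export
rec_duration <- function(rec) {
  (nrow(rec$samples) - 1) / rec$sampling_rate
}

#' Construct a step annotation (sequence of left/right step events)
#'
#' Each event marks the onset of a step on the given side; a sample of a
#' recording is labeled with the side of the most recent event at or before
#' it (last observation carried forward).
#'
#' @param timestamps strictly increasing event times in seconds.
#' @param labels character vector over `"L"`/`"R"`, one per event.
#' @return An object of class `step_annotation`.
#' @export
step_annotation <- function(timestamps, labels) {
  timestamps <- as.numeric(timestamps)
  labels <- as.character(labels)
  if (length(timestamps) != length(labels))
    stop("`timestamps` and `labels` must have the same length")
  if (length(timestamps) < 1L) stop("annotation must contain at least one event")
  if (any(diff(timestamps) <= 0)) stop("`timestamps` must be strictly increasing")
  if (!all(labels %in% c("L", "R")))
    stop("labels must be 'L' or 'R'")
  structure(list(timestamps = timestamps, labels = labels),
            class = "step_annotation")
}

#' Construct a labeled recording (recording + per-sample step side)
#'
#' @param recording an `accel_recording`.
#' @param labels character vector over `"L"`/`"R"`, one label per sample.
#' @return An object of class `labeled_recording`.
#' @seealso [align_annotation()] to derive per-sample labels from sparse
#'   step events.
#' @export
labeled_recording <- function(recording, labels) {
  stopifnot(inherits(recording, "accel_recording"))
  labels <- as.character(labels)
  if (length(labels) != nrow(recording$samples))
    stop("need exactly one label per sample")
  if (!all(labels %in% c("L", "R")))
    stop("labels must be 'L' or 'R'")
  structure(list(recording = recording, labels = labels),
            class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf(
    "<labeled_recording> subject=%s: %d samples at %g Hz, %d step transitions\n",
    x$recording$subject_id, nrow(x$recording$samples),
    x$recording$sampling_rate, labels_to_step_count(x$labels)))
  invisible(x)
}

#' Align a sparse step annotation with a recording
#'
#' Trims both inputs to their overlapping time span, then assigns every
#' sample the side of the most recent annotation event at or before it.
#' Samples preceding the first event (within the overlap) inherit the first
#' event's side. Annotation events mark step onsets, so carrying the last
#' observation forward reproduces the per-time-point left/right labeling
#' used for training.
#'
#' @param rec an `accel_recording`.
#' @param ann a `step_annotation`.
#' @return A [labeled_recording()] trimmed to the overlapping span.
#' @examples
#' rec <- accel_recording(matrix(0:89 / 90, 30, 3), 15)
#' ann <- step_annotation(c(0, 1), c("L", "R"))
#' lr <- align_annotation(rec, ann)
#' table(lr$labels)
#' @export
align_annotation <- function(rec, ann) {
  stopifnot(inherits(rec, "accel_recording"), inherits(ann, "step_annotation"))
  t <- rec_times(rec)
  # labels carry forward, so the annotation span effectively extends from its
  # first event to the end of the recording; only the head is trimmed
  if (ann$timestamps[1] > t[length(t)] + 1e-9)
    stop("annotation starts after the recording ends: no overlap")
  keep <- which(t >= ann$timestamps[1] - 1e-9)
  tk <- t[keep]
  # index of most recent event at or before each sample (0 -> first event)
  idx <- findInterval(tk + 1e-9, ann$timestamps)
  idx[idx == 0L] <- 1L
  labeled_recording(
    accel_recording(rec$samples[keep, , drop = FALSE], rec$sampling_rate,
                    rec$subject_id, rec$device_id, t0 = tk[1]),
    ann$labels[idx])
}
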