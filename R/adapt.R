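#' Personalize a pretrained model on a short labeled calibration walk
#'
#' Domain adaptation for subjects (or devices) the general model handles
#' poorly: all weights are fine-tuned, starting from the pretrained state,
#' on windows drawn exclusively from a short labeled span of the target
#' subject's recording — by default the first 30 seconds, mirroring a
#' calibration walk at the start of a session. Evaluation must use only the
#' remainder of the recording; the adapted span is recorded on the returned
#' handle so [evaluate_adapted()] / [predict_step_count()] can enforce the
#' disjointness.
#'
#' Fine-tuning uses the same Adam settings as pretraining but at most
#' `max_epochs` (default 30) epochs with early stopping patience 5,
#' monitoring accuracy on the adaptation windows themselves (there is no
#' held-out set inside 30 s of data).
#'
#' @param pretrained a trained `step_model`.
#' @param subject a [labeled_recording()] of the target subject.
#' @param adapt_seconds length of the adaptation span in seconds.
#' @param tcfg a [train_config()]; its `max_epochs`/`patience` default to
#'   30/5 for adaptation.
#' @param offset_seconds start of the adaptation span (default 0).
#' @param freeze number of leading layers to keep frozen during
#'   fine-tuning; 0 (the default) fine-tunes all weights.
#' @return A personalized `step_model` with attribute `adapt_span =
#'   c(offset_seconds, offset_seconds + adapt_seconds)`.
#' @export
adapt_model <- function(pretrained, subject, adapt_seconds = 30,
                        tcfg = NULL, offset_seconds = 0, freeze = 0L) {
  stopifnot(inherits(pretrained, "step_model"),
            inherits(subject, "labeled_recording"))
  if (is.null(tcfg))
    tcfg <- train_config(
      batch_size = default_batch_size(pretrained$config$architecture),
      max_epochs = 30L, patience = 5L)
  rec <- subject$recording
  rate <- rec$sampling_rate
  W <- pretrained$config$window_len
  n0 <- floor(offset_seconds * rate) + 1L
  n1 <- floor((offset_seconds + adapt_seconds) * rate)
  if (n1 > nrow(rec$samples) || (n1 - n0 + 1L) < W)
    stop("recording too short: need at least `adapt_seconds` plus one ",
         "window beyond `offset_seconds`")
  idx <- n0:n1
  sub_lr <- labeled_recording(
    accel_recording(rec$samples[idx, , drop = FALSE], rate,
                    rec$subject_id, rec$device_id,
                    t0 = rec$t0 + (n0 - 1L) / rate),
    subject$labels[idx])
  ds <- make_windows(sub_lr, pretrained$config$mode, W)
  m <- pretrained
  if (freeze > 0L)
    for (l in seq_len(min(freeze, length(m$layers))))
      m$layers[[l]]$frozen <- TRUE
  if (tcfg$max_epochs > 0L)
    m <- train_model(m, ds, ds, tcfg)
  for (l in seq_along(m$layers)) m$layers[[l]]$frozen <- NULL
  m$adapt_windows <- dim(ds$x)[1]
  attr(m, "adapt_span") <- c(offset_seconds, offset_seconds + adapt_seconds)
  m
}

#' Evaluate a personalized model on the unadapted remainder of a recording
#'
#' Counts steps on the part of the recording strictly after the adaptation
#' span (asserting the two ranges are disjoint), so personalization is
#' never scored on the data it was tuned on.
#'
#' @param m a `step_model` returned by [adapt_model()] (or any model, with
#'   `from_seconds` given explicitly).
#' @param subject the [labeled_recording()] to score.
#' @param from_seconds start of the evaluation span; defaults to the end of
#'   the model's adaptation span.
#' @return A `step_count_result` (see [predict_step_count()]).
#' @export
evaluate_adapted <- function(m, subject, from_seconds = NULL) {
  span <- attr(m, "adapt_span")
  if (is.null(from_seconds)) {
    if (is.null(span)) stop("model has no recorded adaptation span; ",
                            "pass `from_seconds`")
    from_seconds <- span[2]
  }
  if (!is.null(span) && from_seconds < span[2])
    stop("evaluation span overlaps the adaptation span")
  predict_step_count(m, subject, from_seconds = from_seconds)
}
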