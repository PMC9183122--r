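#' Count steps from a left/right label sequence
#'
#' Each step is a transition from left to right or vice versa, so the step
#' count of a label sequence is the number of positions whose label differs
#' from the previous one. The same rule applied to annotated ground-truth
#' labels gives the reference count.
#'
#' @param labels character vector over `"L"`/`"R"` (may be empty).
#' @return Integer number of transitions.
#' @examples
#' labels_to_step_count(c("L", "R", "L", "R"))  # 3
#' @export
labels_to_step_count <- function(labels) {
  n <- length(labels)
  if (n < 2L) return(0L)
  sum(labels[-1] != labels[-n])
}

#' Step classification accuracy (percent of instants on the correct side)
#'
#' `100 * n_correct / n_total` over per-window left/right predictions.
#'
#' @param pred,truth equal-length label vectors over `"L"`/`"R"`.
#' @return Accuracy in percent.
#' @export
step_classification_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have the same length")
  if (length(pred) < 1L) stop("need at least one label")
  100 * mean(pred == truth)
}

#' Step-count accuracy (percent agreement of predicted and true count)
#'
#' `(1 - |predicted - truth| / truth) * 100`. Symmetric in the direction of
#' the error, and negative when the absolute error exceeds the true count.
#'
#' @param predicted predicted step count.
#' @param truth ground-truth step count (must be >= 1).
#' @return Accuracy in percent (<= 100, possibly negative).
#' @examples
#' step_count_accuracy(98, 100)   # 98
#' step_count_accuracy(102, 100)  # 98
#' @export
step_count_accuracy <- function(predicted, truth) {
  if (truth < 1) stop("`truth` must be at least 1")
  (1 - abs(predicted - truth) / truth) * 100
}

#' Predict a step count for a recording with a trained model
#'
#' Builds stride-1 windows at the model's configured length and feature
#' mode, takes the per-window argmax side (ties resolve to `"L"`), and
#' counts label transitions. When ground-truth labels are available, both
#' accuracy metrics are computed with the truth restricted to the same
#' window-end index range (indices `window_len .. N`), so prediction and
#' truth are compared instant-for-instant.
#'
#' @param m a trained `step_model` (see [build_model()], [train_model()]).
#' @param rec a [labeled_recording()] (accuracies are computed) or a bare
#'   [accel_recording()] (counts only).
#' @param smooth odd window length of an optional majority-vote filter over
#'   the predicted label sequence; `1` (default) disables smoothing.
#' @param from_seconds drop this initial time span before windowing — used
#'   to evaluate a personalized model on data disjoint from its adaptation
#'   span.
#' @return A `step_count_result`: list with `predicted_labels`,
#'   `step_count_predicted`, and — when truth is available —
#'   `step_count_ground_truth`, `step_count_accuracy`,
#'   `step_classification_accuracy`.
#' @export
predict_step_count <- function(m, rec, smooth = 1L, from_seconds = 0) {
  stopifnot(inherits(m, "step_model"))
  lab <- NULL
  if (inherits(rec, "labeled_recording")) {
    lab <- rec$labels
    rec <- rec$recording
  }
  stopifnot(inherits(rec, "accel_recording"))
  if (from_seconds > 0) {
    drop_n <- floor(from_seconds * rec$sampling_rate)
    if (drop_n >= nrow(rec$samples))
      stop("`from_seconds` removes the whole recording")
    keep <- (drop_n + 1L):nrow(rec$samples)
    rec <- accel_recording(rec$samples[keep, , drop = FALSE],
                           rec$sampling_rate, rec$subject_id, rec$device_id,
                           t0 = rec$t0 + drop_n / rec$sampling_rate)
    if (!is.null(lab)) lab <- lab[keep]
  }
  W <- m$config$window_len
  if (nrow(rec$samples) < W)
    stop("recording shorter than one model window (", W, " samples)")
  lr <- labeled_recording(rec, if (is.null(lab))
    rep("L", nrow(rec$samples)) else lab)
  ds <- make_windows(lr, m$config$mode, W)
  pred <- predict_labels(m, ds)
  if (smooth > 1L) pred <- majority_smooth(pred, smooth)
  res <- list(predicted_labels = pred,
              step_count_predicted = labels_to_step_count(pred))
  if (!is.null(lab)) {
    truth <- ds$y
    res$step_count_ground_truth <- labels_to_step_count(truth)
    res$step_classification_accuracy <-
      step_classification_accuracy(pred, truth)
    res$step_count_accuracy <- if (res$step_count_ground_truth >= 1)
      step_count_accuracy(res$step_count_predicted,
                          res$step_count_ground_truth) else NA_real_
  }
  structure(res, class = "step_count_result")
}

#' @export
print.step_count_result <- function(x, ...) {
  cat(sprintf("<step_count_result> predicted %d steps", x$step_count_predicted))
  if (!is.null(x$step_count_ground_truth))
    cat(sprintf(" (truth %d; count accuracy %.2f%%, classification %.2f%%)",
                x$step_count_ground_truth, x$step_count_accuracy,
                x$step_classification_accuracy))
  cat("\n")
  invisible(x)
}

# odd-length sliding majority vote; ends are kept as predicted
majority_smooth <- function(labels, k) {
  stopifnot(k %% 2 == 1)
  n <- length(labels)
  if (n < k) return(labels)
  half <- (k - 1L) %/% 2L
  isR <- as.integer(labels == "R")
  cs <- c(0L, cumsum(isR))
  out <- labels
  for (i in (half + 1L):(n - half)) {
    r <- cs[i + half + 1L] - cs[i - half]
    out[i] <- if (2L * r > k) "R" else if (2L * r < k) "L" else labels[i]
  }
  out
}

#' Write step-count results as a CSV row per recording
#'
#' @param results list of `step_count_result` objects.
#' @param meta data.frame with one row per result (subject_id, device_id,
#'   model, feature_mode, ...).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, meta, path) {
  stopifnot(length(results) == nrow(meta))
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  tab <- cbind(meta, do.call(rbind, lapply(results, function(r)
    data.frame(step_count_predicted = r$step_count_predicted,
               step_count_ground_truth = num(r$step_count_ground_truth),
               step_count_accuracy = num(r$step_count_accuracy),
               step_classification_accuracy =
                 num(r$step_classification_accuracy)))))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
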