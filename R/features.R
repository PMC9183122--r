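#' Compute the ENMO feature (Euclidean norm minus one)
#'
#' The Euclidean norm of the acceleration vector minus 1 g removes the
#' static gravity component regardless of sensor orientation, collapsing
#' the three axes into one orientation-robust scalar:
#' `sqrt(ax^2 + ay^2 + az^2) - 1`. Negative values are kept as-is (no
#' clipping), so a resting sensor reads exactly 0 and sub-1-g instants stay
#' informative.
#'
#' @param rec an [accel_recording()].
#' @return A `feature_series` of mode `"ENMO1"`: a list with `values`
#'   (n x 1 matrix, g), `mode` and `sampling_rate`.
#' @examples
#' rec <- accel_recording(matrix(c(1, 2, 2), 5, 3, byrow = TRUE), 15)
#' compute_enmo(rec)$values[1]  # sqrt(9) - 1 = 2
#' @export
compute_enmo <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  v <- sqrt(rowSums(rec$samples^2)) - 1
  feature_series(matrix(v, ncol = 1), "ENMO1", rec$sampling_rate)
}

feature_series <- function(values, mode = c("RAW3", "ENMO1"), sampling_rate) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  stopifnot(ncol(values) == if (mode == "RAW3") 3L else 1L,
            nrow(values) >= 1L)
  structure(list(values = values, mode = mode, sampling_rate = sampling_rate),
            class = "feature_series")
}

#' Extract the feature series for a given input mode
#'
#' @param rec an [accel_recording()].
#' @param mode `"ENMO1"` for the scalar ENMO feature, `"RAW3"` for the raw
#'   three acceleration channels.
#' @return A `feature_series`.
#' @export
extract_features <- function(rec, mode = c("ENMO1", "RAW3")) {
  mode <- match.arg(mode)
  if (mode == "ENMO1") compute_enmo(rec)
  else feature_series(rec$samples, "RAW3", rec$sampling_rate)
}

#' Build a stride-1 sliding-window dataset from a labeled recording
#'
#' Windows advance one sample at a time; a recording of N samples yields
#' `N - window_len + 1` windows. Each window is labeled with the step side
#' of its *last* sample — the task is "which side is stepping right now,
#' given the recent past" — which keeps the label unambiguous no matter how
#' many steps a window spans (unlike majority labeling, which breaks down
#' for long windows). Windows are strictly causal: window i contains
#' samples `i .. i + window_len - 1` and nothing after.
#'
#' @param lr a [labeled_recording()].
#' @param mode feature mode, `"ENMO1"` or `"RAW3"`.
#' @param window_len window length in samples (30 at 15 Hz = 2 s for the
#'   LSTM; 60 = 4 s for the convolutional models).
#' @param standardize z-score each feature channel over the recording
#'   before windowing. Off by default: the canonical pipeline feeds
#'   unstandardized g-scale features.
#' @return A `windowed_dataset`: list with `x` (n x window_len x channels
#'   array), `y` (character labels `"L"`/`"R"`), `groups` (subject id per
#'   window), `window_len`, `channels`, `mode`, `sampling_rate`, and
#'   `end_index` (index into the recording of each window's last sample).
#' @examples
#' rec <- accel_recording(matrix(rnorm(300), 100, 3), 15)
#' lr <- labeled_recording(rec, rep(c("L", "R"), each = 50))
#' ds <- make_windows(lr, "ENMO1", 30)
#' dim(ds$x)  # 71 x 30 x 1
#' @export
make_windows <- function(lr, mode = c("ENMO1", "RAW3"), window_len,
                         standardize = FALSE) {
  stopifnot(inherits(lr, "labeled_recording"))
  mode <- match.arg(mode)
  window_len <- as.integer(window_len)
  fs <- extract_features(lr$recording, mode)
  if (standardize)
    fs$values <- scale(fs$values)[, , drop = FALSE]
  N <- nrow(fs$values)
  W <- window_len
  if (W < 1L) stop("`window_len` must be at least 1")
  if (W > N) stop("`window_len` (", W, ") exceeds recording length (", N, ")")
  C <- ncol(fs$values)
  n <- N - W + 1L
  x <- array(0, dim = c(n, W, C))
  for (j in seq_len(W)) x[, j, ] <- fs$values[j:(j + n - 1L), ]
  windowed_dataset(x, lr$labels[W:N], rep(lr$recording$subject_id, n),
                   mode, fs$sampling_rate, end_index = W:N)
}

windowed_dataset <- function(x, y, groups, mode, sampling_rate,
                             end_index = NULL) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(y),
            length(groups) == length(y), all(y %in% c("L", "R")))
  structure(list(x = x, y = y, groups = groups,
                 window_len = dim(x)[2], channels = dim(x)[3],
                 mode = mode, sampling_rate = sampling_rate,
                 end_index = end_index),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d windows of %d x %d (%s), %d subject(s)\n",
    dim(x$x)[1], x$window_len, x$channels, x$mode,
    length(unique(x$groups))))
  invisible(x)
}

#' Concatenate windowed datasets (e.g. across subjects)
#'
#' @param ... `windowed_dataset` objects with identical window length,
#'   channel count and mode.
#' @return A single `windowed_dataset`.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "windowed_dataset"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1L)
  W <- parts[[1]]$window_len; C <- parts[[1]]$channels
  mode <- parts[[1]]$mode
  for (p in parts)
    stopifnot(inherits(p, "windowed_dataset"),
              p$window_len == W, p$channels == C, p$mode == mode)
  xm <- do.call(rbind, lapply(parts, function(p) matrix(p$x, dim(p$x)[1])))
  windowed_dataset(array(xm, c(nrow(xm), W, C)),
                   unlist(lapply(parts, `[[`, "y")),
                   unlist(lapply(parts, `[[`, "groups")),
                   mode, parts[[1]]$sampling_rate)
}

#' Cache a windowed dataset on disk
#'
#' Stores the window array as a flat CSV of one row per window plus a JSON
#' sidecar with shape, labels and provenance, so an expensive windowing pass
#' over a long cohort can be reused across runs.
#'
#' @param ds a `windowed_dataset`.
#' @param path base path; `<path>.csv` and `<path>.json` are written.
#' @return base `path`, invisibly.
#' @export
save_windows <- function(ds, path) {
  stopifnot(inherits(ds, "windowed_dataset"))
  n <- dim(ds$x)[1]
  utils::write.table(matrix(ds$x, n), paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(n = n, window_len = ds$window_len, channels = ds$channels,
         mode = ds$mode, sampling_rate = ds$sampling_rate,
         y = ds$y, groups = ds$groups, end_index = ds$end_index),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_windows
#' @export
load_windows <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  xm <- as.matrix(read.csv(paste0(path, ".csv"), header = FALSE))
  windowed_dataset(array(xm, c(meta$n, meta$window_len, meta$channels)),
                   meta$y, meta$groups, meta$mode, meta$sampling_rate,
                   end_index = meta$end_index)
}
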