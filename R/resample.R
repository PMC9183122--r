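#' Resample a recording to a new uniform rate
#'
#' Recordings from different devices arrive at different rates (50 Hz for
#' most modern wearables); the classifiers expect the canonical 15 Hz of the
#' training data, so higher-rate signals are brought down to it before
#' feature extraction.
#'
#' When downsampling, a zero-phase fourth-order Butterworth low-pass at the
#' target Nyquist frequency is applied first (forward-backward filtering on
#' a reflection-padded signal, so there is no phase shift and no edge
#' transient). Samples are then interpolated by a cubic spline onto a
#' uniform grid spanning the original duration. Walking-band content (one
#' to three Hz) passes through essentially unchanged.
#'
#' @param rec an [accel_recording()] with at least 2 samples.
#' @param target_rate desired rate in Hz.
#' @return An [accel_recording()] at `target_rate` covering the same span.
#' @examples
#' rec <- accel_recording(matrix(c(0, 0, 1), 100, 3, byrow = TRUE), 50)
#' resample_recording(rec, 15)
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("`target_rate` must be positive")
  n <- nrow(rec$samples)
  if (n < 2L) stop("cannot resample a recording with fewer than 2 samples")
  if (abs(target_rate - rec$sampling_rate) < 1e-9 * rec$sampling_rate)
    return(rec)
  x <- rec$samples
  if (target_rate < rec$sampling_rate) {
    x <- apply(x, 2, lowpass_zerophase,
               wc = target_rate / rec$sampling_rate)
  }
  t_old <- (seq_len(n) - 1) / rec$sampling_rate
  duration <- t_old[n]
  n_new <- floor(duration * target_rate + 1e-9) + 1L
  t_new <- (seq_len(n_new) - 1) / target_rate
  # odd-reflect a few samples past both ends so the spline's boundary
  # polynomials are anchored on plausible data, not extrapolated
  npad <- min(n - 1L, 12L)
  i_head <- (npad + 1L):2L
  i_tail <- (n - 1L):(n - npad)
  t_pad <- c(t_old[1] - (t_old[i_head] - t_old[1]), t_old,
             t_old[n] + (t_old[n] - t_old[i_tail]))
  y <- vapply(1:3, function(j) {
    v <- x[, j]
    vp <- c(2 * v[1] - v[i_head], v, 2 * v[n] - v[i_tail])
    spline(t_pad, vp, xout = t_new, method = "fmm")$y
  }, numeric(n_new))
  accel_recording(y, target_rate, rec$subject_id, rec$device_id, t0 = rec$t0)
}

# Zero-phase Butterworth low-pass; `wc` is the cutoff as a fraction of the
# input Nyquist. The DC component is removed first (the filter then sees a
# zero-mean signal, so its zero initial state introduces no DC transient)
# and odd reflection padding absorbs what remains of the edge transients.
lowpass_zerophase <- function(v, wc, order = 4) {
  if (wc >= 1) return(v)
  bf <- signal::butter(order, wc, type = "low")
  mu <- mean(v)
  v0 <- v - mu
  npad <- min(length(v0) - 1L, max(10L * order, ceiling(12 / wc)))
  i_head <- (npad + 1):2
  i_tail <- (length(v0) - 1):(length(v0) - npad)
  padded <- c(2 * v0[1] - v0[i_head], v0, 2 * v0[length(v0)] - v0[i_tail])
  filtered <- signal::filtfilt(bf, padded)
  filtered[(npad + 1):(npad + length(v0))] + mu
}
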