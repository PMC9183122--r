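# Shared fixtures, all generated in code.

# recording with arbitrary finite values
tiny_recording <- function(n = 30, rate = 15, seed = 1, subject = "T01") {
  set.seed(seed)
  accel_recording(matrix(rnorm(3 * n, sd = 0.3), n, 3) +
                    matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                  rate, subject_id = subject)
}

# labeled recording with given labels
tiny_labeled <- function(labels, rate = 15, seed = 1, subject = "T01") {
  labeled_recording(tiny_recording(length(labels), rate, seed, subject),
                    labels)
}

# linearly separable windowed dataset: class is encoded in the sign of the
# window mean, so any of the architectures can fit it quickly
separable_windows <- function(n = 400, W = 12, seed = 1, subject = "T01",
                              offset = 0.5) {
  set.seed(seed)
  y <- sample(c("L", "R"), n, replace = TRUE)
  x <- array(rnorm(n * W, sd = 0.2), c(n, W, 1)) +
    array(ifelse(y == "L", offset, -offset), c(n, W, 1))
  steplr:::windowed_dataset(x, y, rep(subject, n), "ENMO1", 15)
}

# small CNN for fast training tests
small_cnn_config <- function(W = 12) {
  model_config("CNN", "ENMO1", window_len = W,
               cnn = list(filters = 8L, dense = 16L))
}
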