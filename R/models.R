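#' Configure one of the three step-classifier architectures
#'
#' All three map a window of acceleration features to a two-class
#' (left/right) probability vector:
#' \describe{
#'   \item{CNN}{one convolution (256 filters, kernel 6, stride 1, ReLU,
#'     valid padding), dropout 0.4, flatten, dense 128 (ReLU) with dropout
#'     0.4, dense 2 + softmax. Default window 60 samples (4 s at 15 Hz).}
#'   \item{WAVENET}{two residual blocks of three dilated *causal*
#'     convolutions each (32 filters, kernel 6, dilations 1, 2, 4) with
#'     gated activation `tanh x sigmoid` and a residual add per layer (1x1
#'     projection where channel counts differ; no skip connection from the
#'     input), dropout 0.4 after each layer, flatten, dense 2 + softmax.
#'     Default window 60 samples.}
#'   \item{LSTM}{two LSTM layers of 256 and 128 cells, both returning their
#'     full output sequence (tanh output / sigmoid recurrent activations);
#'     the whole sequence is flattened into the dense 128 (ReLU) head, then
#'     dense 2 + softmax. Feeding the full sequence (rather than the last
#'     step only) improves gradient flow to early time steps. Default
#'     window 30 samples (2 s at 15 Hz).}
#' }
#'
#' @param architecture `"CNN"`, `"WAVENET"` or `"LSTM"`.
#' @param mode feature mode: `"ENMO1"` (1 channel) or `"RAW3"` (3 channels).
#' @param window_len window length in samples; defaults to 60 for the
#'   convolutional models and 30 for the LSTM.
#' @param cnn,wavenet,lstm named lists overriding architecture
#'   hyperparameters (see Details above for the defaults).
#' @param lstm_head how the LSTM's output sequence feeds the dense head:
#'   `"flatten"` (default) or `"last"` (last time step only).
#' @return A `model_config` list.
#' @export
model_config <- function(architecture = c("CNN", "WAVENET", "LSTM"),
                         mode = c("ENMO1", "RAW3"),
                         window_len = NULL,
                         cnn = list(), wavenet = list(), lstm = list(),
                         lstm_head = c("flatten", "last")) {
  architecture <- match.arg(architecture)
  mode <- match.arg(mode)
  if (is.null(window_len))
    window_len <- if (architecture == "LSTM") 30L else 60L
  cnn_d <- list(filters = 256L, kernel = 6L, stride = 1L, dense = 128L,
                dropout = 0.4)
  wav_d <- list(blocks = 2L, layers_per_block = 3L, filters = 32L,
                kernel = 6L, stride = 1L, dropout = 0.4,
                dilation_rates = c(1L, 2L, 4L), head = "flatten")
  lstm_d <- list(cells = c(256L, 128L), dense = 128L, sequence_output = TRUE)
  cfg <- list(architecture = architecture, mode = mode,
              window_len = as.integer(window_len),
              channels = if (mode == "RAW3") 3L else 1L,
              cnn = utils::modifyList(cnn_d, cnn),
              wavenet = utils::modifyList(wav_d, wavenet),
              lstm = utils::modifyList(lstm_d, lstm),
              lstm_head = match.arg(lstm_head))
  stopifnot(cfg$window_len >= 1L,
            cfg$cnn$dropout >= 0, cfg$cnn$dropout < 1,
            cfg$wavenet$dropout >= 0, cfg$wavenet$dropout < 1)
  structure(cfg, class = "model_config")
}

#' Build an untrained step-classification model
#'
#' Assembles the layer graph of a [model_config()] with deterministic
#' Glorot-uniform weight initialization under the given seed (LSTM forget
#' gate biases start at 1).
#'
#' @param cfg a [model_config()].
#' @param seed integer seed controlling weight initialization.
#' @return A `step_model` handle: list with `config`, `layers` (weights),
#'   `seed` and `history` (per-epoch training records, empty until
#'   [train_model()]).
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  layers <- run_with_seed(seed, build_layers(cfg))
  structure(list(config = cfg, layers = layers, seed = as.integer(seed),
                 history = NULL),
            class = "step_model")
}

build_layers <- function(cfg) {
  C <- cfg$channels
  W <- cfg$window_len
  switch(cfg$architecture,
    CNN = {
      p <- cfg$cnn
      t_out <- W - p$kernel + 1L
      if (t_out < 1L) stop("window_len too short for the CNN kernel")
      list(nn_conv1d(C, p$filters, p$kernel, activation = "relu"),
           nn_dropout(p$dropout),
           nn_flatten(),
           nn_dense(t_out * p$filters, p$dense, "relu"),
           nn_dropout(p$dropout),
           nn_dense(p$dense, 2L, "linear"))
    },
    WAVENET = {
      p <- cfg$wavenet
      layers <- list()
      in_ch <- C
      for (b in seq_len(p$blocks)) {
        for (l in seq_len(p$layers_per_block)) {
          layers <- c(layers, list(
            nn_gated_residual(in_ch, p$filters, p$kernel,
                              p$dilation_rates[l]),
            nn_dropout(p$dropout)))
          in_ch <- p$filters
        }
      }
      if (identical(p$head, "last")) {
        # diagnostic head: classify from the final position only, so the
        # output depends on exactly the receptive field of that position
        c(layers, list(list(type = "last_step", par = NULL),
                       nn_dense(p$filters, 2L, "linear")))
      } else {
        c(layers, list(nn_flatten(), nn_dense(W * p$filters, 2L, "linear")))
      }
    },
    LSTM = {
      p <- cfg$lstm
      layers <- list()
      in_ch <- C
      for (h in p$cells) {
        layers <- c(layers, list(nn_lstm(in_ch, h)))
        in_ch <- h
      }
      head_dim <- if (cfg$lstm_head == "flatten") W * in_ch else in_ch
      c(layers,
        list(if (cfg$lstm_head == "flatten") nn_flatten()
             else list(type = "last_step", par = NULL)),
        list(nn_dense(head_dim, p$dense, "relu"),
             nn_dense(p$dense, 2L, "linear")))
    },
    stop("unknown architecture: ", cfg$architecture))
}

#' @export
print.step_model <- function(x, ...) {
  cat(sprintf("<step_model> %s (%s, window %d): %d parameters%s\n",
              x$config$architecture, x$config$mode, x$config$window_len,
              n_params(x),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}

#' Total number of trainable parameters of a model
#'
#' @param m a `step_model`.
#' @return Integer parameter count (summed over all weight arrays).
#' @export
n_params <- function(m) {
  stopifnot(inherits(m, "step_model"))
  sum(vapply(m$layers, function(l)
    if (is.null(l$par)) 0L else sum(vapply(l$par, length, integer(1))),
    integer(1)))
}

#' Class probabilities for every window of a dataset
#'
#' Runs the model in inference mode (dropout disabled), batched to bound
#' memory. Deterministic for fixed weights.
#'
#' @param m a `step_model`.
#' @param ds a `windowed_dataset` (or a bare n x W x C array) matching the
#'   model's window length and channel count.
#' @param batch_size forward-pass batch size.
#' @return An n x 2 matrix of probabilities, columns `L` and `R`; rows sum
#'   to 1.
#' @export
predict_proba <- function(m, ds, batch_size = 1024L) {
  stopifnot(inherits(m, "step_model"))
  x <- if (inherits(ds, "windowed_dataset")) ds$x else ds
  d <- dim(x)
  if (length(d) != 3L || d[2] != m$config$window_len ||
      d[3] != m$config$channels)
    stop(sprintf("input shape (%s) does not match model window %d x %d",
                 paste(d, collapse = " x "),
                 m$config$window_len, m$config$channels))
  n <- d[1]
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("L", "R")))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- x[idx, , , drop = FALSE]
    out[idx, ] <- softmax_rows(nn_forward(m$layers, xb, training = FALSE)$out)
  }
  out
}

#' Hard left/right labels for every window (argmax; ties resolve to "L")
#'
#' @inheritParams predict_proba
#' @return Character vector of `"L"`/`"R"`.
#' @export
predict_labels <- function(m, ds, batch_size = 1024L) {
  p <- predict_proba(m, ds, batch_size)
  c("L", "R")[max.col(p, ties.method = "first")]
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `config.json` (architecture and
#' hyperparameters) plus `weights.rds` (all weight arrays, bit-exact).
#'
#' @param m a `step_model`.
#' @param dir checkpoint directory (created if missing).
#' @return `save_model()`: `dir` invisibly; `load_model()`: a `step_model`
#'   identical to the one saved.
#' @export
save_model <- function(m, dir) {
  stopifnot(inherits(m, "step_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(m$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(layers = m$layers, seed = m$seed, history = m$history),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfg <- model_config(cfgj$architecture, cfgj$mode, cfgj$window_len,
                      cnn = cfgj$cnn, wavenet = cfgj$wavenet,
                      lstm = cfgj$lstm, lstm_head = cfgj$lstm_head)
  w <- readRDS(file.path(dir, "weights.rds"))
  structure(list(config = cfg, layers = w$layers, seed = w$seed,
                 history = w$history),
            class = "step_model")
}
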