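#' Configure the training protocol
#'
#' Defaults follow the cross-validated protocol the architectures were
#' selected with: Adam (learning rate 0.001, beta1 0.9, beta2 0.999,
#' epsilon 1e-7, no amsgrad), categorical cross-entropy, at most 50 epochs,
#' early stopping with patience 10 monitoring *validation step-classification
#' accuracy* (more relevant to the goal than validation loss), and batch
#' size 256 for the convolutional models / 512 for the LSTM.
#'
#' @param batch_size windows per optimization step.
#' @param learning_rate,beta1,beta2,epsilon Adam settings.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation-accuracy improvement before
#'   stopping (must not exceed `max_epochs`).
#' @param seed master seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 256L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         max_epochs = 50L, patience = 10L, seed = 1L) {
  stopifnot(batch_size >= 1L, max_epochs >= 0L, patience <= max_epochs ||
              max_epochs == 0L)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Default batch size per architecture (256 convolutional, 512 LSTM)
#' @param architecture `"CNN"`, `"WAVENET"` or `"LSTM"`.
#' @return Integer batch size.
#' @export
default_batch_size <- function(architecture) {
  if (architecture == "LSTM") 512L else 256L
}

#' Split subjects into training and validation sets
#'
#' Splitting is by subject, never by window, so no individual contributes
#' data to both sides. Deterministic for a given seed.
#'
#' @param subject_ids character vector of distinct subject ids.
#' @param n_val number of validation subjects (the canonical protocol holds
#'   out 2 of 30).
#' @param seed integer seed.
#' @return List with `train` and `val` id vectors (disjoint, exhaustive).
#' @export
split_subjects <- function(subject_ids, n_val = 2L, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (n_val >= length(subject_ids))
    stop("`n_val` must be smaller than the number of subjects")
  if (n_val < 1L) stop("`n_val` must be at least 1")
  shuffled <- run_with_seed(seed, sample(subject_ids))
  list(train = sort(shuffled[-(seq_len(n_val))]),
       val = sort(shuffled[seq_len(n_val)]))
}

label_onehot <- function(y) {
  cbind(L = as.numeric(y == "L"), R = as.numeric(y == "R"))
}

#' Train a step classifier with early stopping
#'
#' Minimizes categorical cross-entropy with Adam over shuffled mini-batches.
#' After every epoch the validation step-classification accuracy is
#' measured; the weights of the best epoch are kept and training stops once
#' `patience` epochs pass without improvement. The returned model is
#' restored to its best-validation state.
#'
#' @param m a `step_model` (untrained or pretrained).
#' @param train,val `windowed_dataset`s matching the model's shape.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return The trained `step_model`; `$history` holds per-epoch records
#'   (`epoch`, `train_loss`, `train_acc`, `val_acc`, `best`).
#' @export
train_model <- function(m, train, val, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(m, "step_model"), inherits(cfg, "train_config"))
  for (ds in list(train, val))
    if (dim(ds$x)[2] != m$config$window_len ||
        dim(ds$x)[3] != m$config$channels)
      stop("dataset shape does not match the model configuration")
  n <- dim(train$x)[1]
  if (n < 1L || dim(val$x)[1] < 1L) stop("datasets must be nonempty")
  y_train <- label_onehot(train$y)
  layers <- deep_copy_layers(m$layers)  # optimizer updates weights in place
  opt <- adam_init(layers)
  best <- list(acc = -Inf, layers = layers, epoch = 0L)
  wait <- 0L
  hist <- NULL
  step <- 0L
  run_with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        xb <- train$x[idx, , , drop = FALSE]
        yb <- y_train[idx, , drop = FALSE]
        fw <- nn_forward(layers, xb, training = TRUE)
        ls <- softmax_xent(fw$out, yb)
        if (!is.finite(ls$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        bw <- nn_backward(layers, fw$caches, ls$dlogits)
        step <- step + 1L
        adam_step(layers, bw$grads, opt, step,
                  lr = cfg$learning_rate, beta1 = cfg$beta1,
                  beta2 = cfg$beta2, eps = cfg$epsilon)
        ep_loss <- ep_loss + ls$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(fw$out, ties.method = "first") ==
                max.col(yb, ties.method = "first"))
      }
      m$layers <- layers
      val_acc <- step_classification_accuracy(predict_labels(m, val), val$y)
      improved <- val_acc > best$acc
      if (improved) {
        best <- list(acc = val_acc, layers = deep_copy_layers(layers),
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
      }
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = ep_loss / n,
        train_acc = 100 * ep_correct / n, val_acc = val_acc,
        best = improved))
      if (verbose)
        message(sprintf(
          "epoch %3d  loss %.4f  train acc %6.2f%%  val acc %6.2f%%%s",
          epoch, ep_loss / n, 100 * ep_correct / n, val_acc,
          if (improved) "  *" else ""))
      if (wait >= cfg$patience) break
    }
  })
  m$layers <- best$layers
  m$history <- hist
  m$best_epoch <- best$epoch
  m$best_val_acc <- best$acc
  m
}

#' Subject-wise shuffled cross-validation
#'
#' Repeats `n_iter` times: shuffle-split the subjects into training and
#' `n_val` held-out validation subjects, train a fresh model, and measure
#' per held-out subject both the step-classification accuracy and the
#' transition-based step-count accuracy. Iteration `i` uses seed
#' `tcfg$seed + i` for its split, weight initialization and shuffling, so a
#' run is reproducible from the master seed alone.
#'
#' @param data named list of per-subject `windowed_dataset`s (names are
#'   subject ids).
#' @param mcfg a [model_config()].
#' @param tcfg a [train_config()].
#' @param n_iter number of shuffled iterations (the canonical protocol uses
#'   70).
#' @param n_val held-out subjects per iteration.
#' @param verbose print progress.
#' @return A `cv_result`: `$iterations` (one row per iteration with mean
#'   accuracies over its validation subjects), `$per_subject` (one row per
#'   validation subject per iteration), `$summary` (means and standard
#'   deviations across iterations).
#' @export
cross_validate <- function(data, mcfg, tcfg = train_config(), n_iter = 70L,
                           n_val = 2L, verbose = FALSE) {
  stopifnot(is.list(data), length(data) >= n_val + 1L,
            !is.null(names(data)), all(nzchar(names(data))))
  ids <- names(data)
  iter_rows <- NULL
  subj_rows <- NULL
  for (i in seq_len(n_iter)) {
    seed_i <- tcfg$seed + i
    sp <- split_subjects(ids, n_val, seed_i)
    stopifnot(length(intersect(sp$train, sp$val)) == 0L)
    train_ds <- bind_windows(data[sp$train])
    val_ds <- bind_windows(data[sp$val])
    stopifnot(!any(unique(train_ds$groups) %in% unique(val_ds$groups)))
    tcfg_i <- tcfg
    tcfg_i$seed <- seed_i
    mdl <- train_model(build_model(mcfg, seed_i), train_ds, val_ds, tcfg_i,
                       verbose = verbose)
    per <- lapply(sp$val, function(sid) {
      ds <- data[[sid]]
      pred <- predict_labels(mdl, ds)
      true_count <- labels_to_step_count(ds$y)
      pred_count <- labels_to_step_count(pred)
      data.frame(
        iter = i, subject_id = sid,
        step_classification_accuracy =
          step_classification_accuracy(pred, ds$y),
        step_count_predicted = pred_count,
        step_count_ground_truth = true_count,
        step_count_accuracy = if (true_count >= 1)
          step_count_accuracy(pred_count, true_count) else NA_real_)
    })
    per <- do.call(rbind, per)
    subj_rows <- rbind(subj_rows, per)
    iter_rows <- rbind(iter_rows, data.frame(
      iter = i,
      train_subjects = paste(sp$train, collapse = ";"),
      val_subjects = paste(sp$val, collapse = ";"),
      step_classification_accuracy =
        mean(per$step_classification_accuracy),
      step_count_accuracy = mean(per$step_count_accuracy)))
    if (verbose)
      message(sprintf("iteration %d/%d: classification %.2f%%, count %.2f%%",
                      i, n_iter,
                      iter_rows$step_classification_accuracy[i],
                      iter_rows$step_count_accuracy[i]))
  }
  structure(list(
    iterations = iter_rows, per_subject = subj_rows,
    summary = list(
      mean_step_classification_accuracy =
        mean(iter_rows$step_classification_accuracy),
      sd_step_classification_accuracy =
        stats::sd(iter_rows$step_classification_accuracy),
      mean_step_count_accuracy = mean(iter_rows$step_count_accuracy),
      sd_step_count_accuracy = stats::sd(iter_rows$step_count_accuracy))),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<cv_result> %d iterations\n",
    "  step classification accuracy: %.2f%% (sd %.2f)\n",
    "  step count accuracy:          %.2f%% (sd %.2f)\n"),
    nrow(x$iterations),
    s$mean_step_classification_accuracy, s$sd_step_classification_accuracy,
    s$mean_step_count_accuracy, s$sd_step_count_accuracy))
  invisible(x)
}
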