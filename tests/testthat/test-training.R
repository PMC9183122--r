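test_that("subject splits are disjoint, exhaustive and seed-deterministic", {
  ids <- sprintf("S%02d", 1:30)
  sp <- split_subjects(ids, n_val = 2, seed = 7)
  expect_length(sp$train, 28)
  expect_length(sp$val, 2)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)
  expect_identical(sp, split_subjects(ids, 2, seed = 7))
  expect_false(identical(sp$val, split_subjects(ids, 2, seed = 8)$val))
  expect_error(split_subjects(ids[1:2], 2), "smaller")
})

test_that("training fits a separable problem and restores the best epoch", {
  tr <- separable_windows(400, seed = 1)
  va <- separable_windows(200, seed = 2)
  tcfg <- train_config(batch_size = 64, max_epochs = 10, patience = 5,
                       seed = 1)
  m <- train_model(build_model(small_cnn_config(), 1), tr, va, tcfg)
  expect_gt(max(m$history$train_acc), 95)
  # the restored model reproduces the best recorded validation accuracy
  acc <- step_classification_accuracy(predict_labels(m, va), va$y)
  expect_equal(acc, max(m$history$val_acc))
  expect_equal(acc, m$best_val_acc)
})

test_that("early stopping halts within `patience` epochs of the best", {
  tr <- separable_windows(300, seed = 3)
  va <- separable_windows(100, seed = 4)
  tcfg <- train_config(batch_size = 64, max_epochs = 40, patience = 3,
                       seed = 1)
  m <- train_model(build_model(small_cnn_config(), 1), tr, va, tcfg)
  best_epoch <- which.max(m$history$val_acc)
  expect_lte(nrow(m$history), best_epoch + 3)
})

test_that("training is reproducible from the seed", {
  tr <- separable_windows(200, seed = 5)
  va <- separable_windows(80, seed = 6)
  tcfg <- train_config(batch_size = 64, max_epochs = 4, patience = 4,
                       seed = 11)
  m1 <- train_model(build_model(small_cnn_config(), 2), tr, va, tcfg)
  m2 <- train_model(build_model(small_cnn_config(), 2), tr, va, tcfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)
})

test_that("non-finite loss aborts with a diagnostic", {
  tr <- separable_windows(100, seed = 7)
  tr$x[1, , ] <- NaN
  tcfg <- train_config(batch_size = 50, max_epochs = 2, patience = 2)
  expect_error(
    train_model(build_model(small_cnn_config(), 1), tr, tr, tcfg),
    "non-finite loss")
})

test_that("cross-validation keeps subjects apart and summarizes iterations", {
  cohort <- simulate_cohort(4, seed = 2, duration = 30)
  ds <- lapply(cohort, function(s) make_windows(s$recording, "ENMO1", 12))
  mcfg <- small_cnn_config()
  tcfg <- train_config(batch_size = 128, max_epochs = 2, patience = 2,
                       seed = 5)
  cv <- cross_validate(ds, mcfg, tcfg, n_iter = 2, n_val = 1)
  expect_equal(nrow(cv$iterations), 2)
  expect_equal(nrow(cv$per_subject), 2)
  for (i in 1:2) {
    tr_ids <- strsplit(cv$iterations$train_subjects[i], ";")[[1]]
    va_ids <- strsplit(cv$iterations$val_subjects[i], ";")[[1]]
    expect_length(intersect(tr_ids, va_ids), 0)
    expect_setequal(c(tr_ids, va_ids), names(ds))
  }
  expect_true(all(cv$iterations$step_classification_accuracy >= 0 &
                    cv$iterations$step_classification_accuracy <= 100))
  expect_true(all(cv$iterations$step_count_accuracy <= 100))

  # one iteration is exactly one seeded train/eval run
  cv1 <- cross_validate(ds, mcfg, tcfg, n_iter = 1, n_val = 1)
  sp <- split_subjects(names(ds), 1, seed = tcfg$seed + 1)
  tcfg1 <- tcfg; tcfg1$seed <- tcfg$seed + 1
  m <- train_model(build_model(mcfg, tcfg$seed + 1),
                   bind_windows(ds[sp$train]), bind_windows(ds[sp$val]),
                   tcfg1)
  pred <- predict_labels(m, ds[[sp$val]])
  expect_equal(cv1$per_subject$step_classification_accuracy,
               step_classification_accuracy(pred, ds[[sp$val]]$y))
})

test_that("zero-epoch adaptation is the identity; spans stay disjoint", {
  sim <- simulate_subject(gait_params(duration = 60, seed = 9))
  m <- build_model(small_cnn_config(W = 30), seed = 1)
  tcfg0 <- train_config(max_epochs = 0, patience = 0)
  same <- adapt_model(m, sim$recording, adapt_seconds = 30, tcfg = tcfg0)
  expect_identical(same$layers, m$layers)
  expect_equal(attr(same, "adapt_span"), c(0, 30))
  # evaluation must not touch the adaptation span
  expect_error(evaluate_adapted(same, sim$recording, from_seconds = 10),
               "overlaps")
  res <- evaluate_adapted(same, sim$recording)
  expect_true(is.finite(res$step_count_accuracy))

  short <- simulate_subject(gait_params(duration = 20, seed = 9))
  expect_error(adapt_model(m, short$recording, adapt_seconds = 30,
                           tcfg = tcfg0), "too short")
})

test_that("adaptation trains only on the requested span", {
  sim <- simulate_subject(gait_params(duration = 45, seed = 10))
  m0 <- build_model(small_cnn_config(W = 30), seed = 2)
  tcfg <- train_config(batch_size = 128, max_epochs = 2, patience = 2,
                       seed = 3)
  m1 <- adapt_model(m0, sim$recording, adapt_seconds = 30, tcfg = tcfg)
  expect_false(identical(m1$layers, m0$layers))
  expect_gte(nrow(m1$history), 1)
  # 30 s at 15 Hz = 450 samples -> 450 - W + 1 adaptation windows
  expect_equal(m1$adapt_windows, 450 - 30 + 1)
})

test_that("frozen leading layers keep their pretrained weights", {
  sim <- simulate_subject(gait_params(duration = 45, seed = 12))
  m0 <- build_model(small_cnn_config(W = 30), seed = 4)
  tcfg <- train_config(batch_size = 128, max_epochs = 2, patience = 2,
                       seed = 5)
  m1 <- adapt_model(m0, sim$recording, adapt_seconds = 30, tcfg = tcfg,
                    freeze = 1L)
  expect_identical(m1$layers[[1]]$par, m0$layers[[1]]$par)  # conv frozen
  expect_false(identical(m1$layers[[4]]$par, m0$layers[[4]]$par))
  expect_null(m1$layers[[1]]$frozen)
})
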