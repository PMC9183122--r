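# Closed-form parameter counts, derived by hand from the architecture
# definitions (conv: (kernel*in_ch + 1)*filters; dense: (in + 1)*out;
# LSTM: 4*(units*(in + units) + units); gated conv carries two kernels).
expected_cnn_params <- function(C, W) {
  conv <- (6 * C + 1) * 256
  dense1 <- ((W - 5) * 256 + 1) * 128
  conv + dense1 + (128 + 1) * 2
}
expected_wavenet_params <- function(C, W) {
  gated <- function(cin) 2 * (6 * cin + 1) * 32
  proj <- C * 32 + 32                     # only the first layer reshapes
  gated(C) + proj + 5 * gated(32) + (W * 32 + 1) * 2
}
expected_lstm_params <- function(C, W) {
  l1 <- 4 * (256 * (C + 256) + 256)
  l2 <- 4 * (128 * (256 + 128) + 128)
  l1 + l2 + (W * 128 + 1) * 128 + (128 + 1) * 2
}

test_that("parameter counts match hand-derived closed forms", {
  cases <- expand.grid(arch = c("CNN", "WAVENET", "LSTM"),
                       mode = c("ENMO1", "RAW3"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cfg <- model_config(cases$arch[i], cases$mode[i])
    m <- build_model(cfg, seed = 1)
    C <- cfg$channels; W <- cfg$window_len
    expected <- switch(cases$arch[i],
                       CNN = expected_cnn_params(C, W),
                       WAVENET = expected_wavenet_params(C, W),
                       LSTM = expected_lstm_params(C, W))
    expect_equal(n_params(m), expected,
                 info = paste(cases$arch[i], cases$mode[i]))
  }
  # spot values: first CNN conv layer alone is (6*3+1)*256 = 4864 weights
  cnn <- build_model(model_config("CNN", "RAW3"), 1)
  expect_equal(sum(lengths(cnn$layers[[1]]$par)), 4864)
})

test_that("the LSTM configuration reports layer widths 256 then 128", {
  cfg <- model_config("LSTM", "RAW3")
  expect_equal(cfg$lstm$cells, c(256L, 128L))
  m <- build_model(cfg, 1)
  expect_equal(m$layers[[1]]$units, 256L)
  expect_equal(m$layers[[2]]$units, 128L)
  expect_equal(cfg$window_len, 30L)  # 2 s at 15 Hz
})

test_that("predictions are probability rows and deterministic", {
  set.seed(20)
  x <- array(rnorm(1000 * 12), c(1000, 12, 1))
  for (arch in c("CNN", "WAVENET", "LSTM")) {
    cfg <- model_config(arch, "ENMO1", window_len = 12,
                        cnn = list(filters = 8L, dense = 8L),
                        wavenet = list(filters = 4L),
                        lstm = list(cells = c(8L, 4L), dense = 8L))
    m <- build_model(cfg, seed = 3)
    p1 <- predict_proba(m, x)
    expect_equal(dim(p1), c(1000L, 2L))
    expect_lt(max(abs(rowSums(p1) - 1)), 1e-6)
    expect_true(all(p1 >= 0))
    # dropout is disabled at inference: repeated prediction is identical
    p2 <- predict_proba(m, x)
    expect_identical(p1, p2)
    expect_true(all(predict_labels(m, x) %in% c("L", "R")))
  }
})

test_that("identical seeds build identical models; shapes are validated", {
  cfg <- model_config("CNN", "ENMO1", window_len = 12,
                      cnn = list(filters = 4L, dense = 4L))
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_identical(m1$layers, m2$layers)
  x_bad <- array(0, c(5, 30, 1))
  expect_error(predict_proba(m1, x_bad), "does not match")
  expect_error(model_config("MLP"))
})

test_that("the dilated stack's last position sees exactly its receptive field", {
  # 1 block, kernel 2, dilations 1,2,4 -> receptive field 1 + 1+2+4 = 8;
  # with the diagnostic last-step head, samples before that cannot matter
  cfg <- model_config("WAVENET", "ENMO1", window_len = 20,
                      wavenet = list(blocks = 1L, kernel = 2L, filters = 4L,
                                     head = "last"))
  m <- build_model(cfg, seed = 2)
  set.seed(2)
  x <- array(rnorm(20), c(1, 20, 1))
  base <- predict_proba(m, x)
  inside <- x; inside[1, 20, 1] <- inside[1, 20, 1] + 1
  expect_gt(max(abs(predict_proba(m, inside) - base)), 1e-8)
  outside <- x; outside[1, 1:12, 1] <- rnorm(12)
  expect_lt(max(abs(predict_proba(m, outside) - base)), 1e-12)

  # under the default flatten head the whole window matters
  cfg2 <- model_config("WAVENET", "ENMO1", window_len = 20,
                       wavenet = list(blocks = 1L, kernel = 2L, filters = 4L))
  m2 <- build_model(cfg2, seed = 2)
  base2 <- predict_proba(m2, x)
  expect_gt(max(abs(predict_proba(m2, outside) - base2)), 1e-8)
})

test_that("checkpoints reload bit-exact", {
  cfg <- model_config("WAVENET", "ENMO1", window_len = 12,
                      wavenet = list(filters = 4L))
  m <- build_model(cfg, seed = 5)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir)
  expect_identical(back$layers, m$layers)
  set.seed(1)
  x <- array(rnorm(7 * 12), c(7, 12, 1))
  expect_identical(predict_proba(back, x), predict_proba(m, x))
})
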