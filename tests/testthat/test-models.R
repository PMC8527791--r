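test_that("dilated convolution matches hand-checkable cases", {
  # all-zero weights and bias: pre-activation zero, ReLU zero
  l0 <- conv_layer_spec(1, 2, 3, 1, weights = array(0, c(2, 1, 3)),
                        bias = c(0, 0))
  expect_equal(dilated_conv1d(1:8, l0), matrix(0, 2, 8))

  # centre-spike filter with identity activation reproduces the input
  spike <- array(c(0, 0, 1, 0, 0), c(1, 1, 5))
  lid <- conv_layer_spec(1, 1, 5, 1, weights = spike, bias = 0,
                         activation = "identity")
  expect_equal(dilated_conv1d(1:8, lid), matrix(1:8, 1, 8))

  # dilation-2 difference filter against the direct-summation oracle
  w <- array(c(1, 0, -1), c(1, 1, 3))
  ld <- conv_layer_spec(1, 1, 3, 2, weights = w, bias = 0,
                        activation = "identity")
  expect_equal(dilated_conv1d(1:8, ld),
               conv_oracle(1:8, w, 0, 2))

  expect_error(dilated_conv1d(matrix(1:8, 2), lid), "channels")
})

test_that("dilated convolution agrees with the oracle on random instances", {
  set.seed(99)
  for (i in 1:25) {
    ci <- sample(1:3, 1); co <- sample(1:3, 1)
    k <- sample(c(3L, 5L), 1); d <- sample(1:3, 1)
    len <- sample(8:20, 1)
    w <- array(rnorm(co * ci * k), c(co, ci, k))
    b <- rnorm(co)
    x <- matrix(rnorm(ci * len), ci)
    l <- conv_layer_spec(ci, co, k, d, weights = w, bias = b,
                         activation = "identity")
    expect_equal(dilated_conv1d(x, l), conv_oracle(x, w, b, d),
                 tolerance = 1e-6)
  }
})

test_that("receptive field follows the stride-1 dilation formula", {
  expect_identical(receptive_field(c(5, 5), c(1, 2)), 13L)
  expect_identical(receptive_field(5, 1), 5L)
  # default four-layer stack vs the per-layer recurrence oracle
  rf <- 1L
  for (l in 1:4) rf <- rf + (5L - 1L) * 2L
  expect_identical(receptive_field(rep(5, 4), rep(2, 4)), rf)
  expect_error(receptive_field(integer(0), integer(0)), "at least one")
  expect_error(receptive_field(c(5, 5), c(1, 2), c(1, 2)), "stride")
})

test_that("the default multi-task architecture matches its specification", {
  m <- build_model("cnn-multi", seed = 1)
  types <- vapply(m$net, `[[`, "", "type")
  expect_identical(types, c("avgpool",
                            rep(c("conv1d", "batchnorm", "relu"), 4),
                            "flatten",
                            "dense", "relu", "dropout",
                            "dense", "relu", "dropout",
                            "dense"))
  convs <- Filter(function(l) l$type == "conv1d", m$net)
  expect_identical(vapply(convs, `[[`, 0L, "out_ch"), c(75L, 150L, 225L, 300L))
  expect_true(all(vapply(convs, `[[`, 0L, "dilation") == 2L))
  expect_true(all(vapply(convs, `[[`, 0L, "filter_size") == 5L))
  final <- m$net[[length(m$net)]]
  expect_identical(final$out_dim, 10L)

  s <- build_model("cnn-single", traits = "LMA", seed = 1)
  expect_identical(s$net[[length(s$net)]]$out_dim, 1L)
  expect_identical(vapply(s$net, `[[`, "", "type"), types)

  # parameter count vs a per-layer hand sum
  ch <- c(1, 75, 150, 225, 300)
  n_conv <- sum(5 * ch[-5] * ch[-1] + ch[-1])
  n_bn <- sum(2 * ch[-1])
  n_fc <- (300 * 200) * 800 + 800 + 800 * 200 + 200 + 200 * 10 + 10
  ns <- asNamespace("spectratraits")
  expect_identical(ns$nn_count_params(m$net), n_conv + n_bn + n_fc)

  expect_error(build_model("resnet"), "unknown")
  expect_error(build_model("cnn-single", traits = c("LMA", "J")), "single")
})

test_that("ensemble prediction is the arithmetic mean of its members", {
  s <- make_spectra(4L)
  m10 <- stub_model(10); m20 <- stub_model(20)
  out <- ensemble_predict(list(m10, m20), s)
  expect_true(all(out == 15))
  expect_identical(dim(out), c(4L, 10L))
  one <- ensemble_predict(list(m10, m10, m10), s)
  expect_true(all(one == 10))
  expect_error(ensemble_predict(list(), s), "at least one")
  partial <- stub_model(5, traits = c("LMA", "J"))
  expect_error(ensemble_predict(list(m10, partial), s), "all requested")
})

test_that("PLSR range matching picks the largest contained range", {
  expect_equal(match_plsr_range(make_spectra(1L, 400:950)), c(400, 900))
  expect_equal(match_plsr_range(make_spectra(1L, 400:2399)), c(400, 2400))
  expect_equal(match_plsr_range(make_spectra(1L, 400:1650)), c(400, 1000))
  expect_equal(match_plsr_range(make_spectra(1L, 390:1700)), c(400, 1700))
  expect_error(match_plsr_range(make_spectra(1L, 450:950)), "narrower")
  expect_error(match_plsr_range(make_spectra(1L, 400:880)), "narrower")
})

test_that("model archives round-trip and reject tampered configurations", {
  m <- build_model("mlp", cnn_config(channels = c(4L, 8L), fc = c(8L, 4L),
                                     input_length = 100L), seed = 2)
  m$scaler <- list(mean = setNames(rep(0, 10), trait_names()),
                   sd = setNames(rep(1, 10), trait_names()))
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$config, m$config)
  x <- matrix(runif(2 * 100), 2, dimnames = list(NULL, 400:499))
  expect_identical(predict(m, x), predict(m2, x))

  arch <- readRDS(f)
  arch$model$config$fc <- c(999L, 4L)
  saveRDS(arch, f)
  expect_error(load_model(f), "hash mismatch")
})
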