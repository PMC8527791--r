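# Training-dynamics properties at reduced problem sizes (small networks, few
# hundred samples) so the whole suite stays CPU-friendly; see the methods
# vignette for the sizing rationale.

tiny_cfg <- function(out = 10L, dropout = 0) {
  cnn_config(output_size = out, channels = c(8L, 16L), fc = c(64L, 32L),
             dropout = dropout)
}

r2_of <- function(y, p) 1 - sum((y - p)^2) / sum((y - mean(y))^2)

test_that("the multi-task CNN recovers noiseless planted traits", {
  # traits are noiseless functionals of the spectrum, so regularisation is
  # switched off (dropout 0, no augmentation: the +/-5 nm shift would alias
  # the red-edge position that encodes Narea) and the fit is run to
  # convergence at a raised learning rate suited to the small network
  d <- generate_dataset(sim_config(n = 300, seed = 1, label_noise = 0,
                                   missingness = no_missing()))
  s <- trim_to_range(jump_correct(d$spectra))
  sp <- split_dataset(filter_outliers(s)$kept, d$traits, seed = 1)
  m <- build_model("cnn-multi", tiny_cfg(), seed = 1)
  cfg <- train_config(epochs = 300, interval = 10, seed = 1,
                      learning_rate = 3e-4, shift_rate = 0,
                      spectral_trim = FALSE)
  r <- train_with_early_stopping(m, sp, cfg)
  va <- split_part(sp, "validation")
  pred <- predict(r$model, va$x)
  for (trait in c("LMA", "Narea"))
    expect_gt(r2_of(va$y[, trait], pred[, trait]), 0.95)
})

test_that("multi-task training is not materially worse than single-task", {
  # the shared-trunk benefit is a noise-averaging effect, so it is probed in
  # the regime where single-task models overfit: few training samples and
  # strong independent label noise on strongly correlated traits
  d <- generate_dataset(sim_config(n = 130, seed = 2, label_noise = 0.6,
                                   missingness = no_missing()))
  s <- trim_to_range(jump_correct(d$spectra))
  sp <- split_dataset(filter_outliers(s)$kept, d$traits, seed = 2)
  cfg <- train_config(epochs = 200, interval = 10, seed = 2,
                      learning_rate = 3e-4, shift_rate = 0,
                      spectral_trim = FALSE)
  multi <- train_with_early_stopping(build_model("cnn-multi", tiny_cfg(),
                                                 seed = 2), sp, cfg)$model
  probe <- c("LMA", "Narea", "SPAD")
  te <- split_part(sp, "test")
  pm <- predict(multi, te$x)
  multi_r2 <- vapply(probe, function(tr) r2_of(te$y[, tr], pm[, tr]), numeric(1))
  single_r2 <- vapply(probe, function(tr) {
    m1 <- build_model("cnn-single", tiny_cfg(1L), traits = tr, seed = 2)
    f <- train_with_early_stopping(m1, sp, cfg)$model
    r2_of(te$y[, tr], predict(f, te$x)[, tr])
  }, numeric(1))
  expect_gte(mean(multi_r2), mean(single_r2) - 0.05)
})

test_that("MLP and LSTM train end to end at toy scale", {
  d <- generate_dataset(sim_config(n = 80, seed = 3,
                                   missingness = no_missing()))
  s <- trim_to_range(jump_correct(d$spectra))
  sp <- split_dataset(filter_outliers(s)$kept, d$traits, seed = 3)
  cfg <- train_config(epochs = 20, interval = 10, batch_size = 16, seed = 3,
                      shift_rate = 0, spectral_trim = FALSE)

  mlp <- build_model("mlp", cnn_config(channels = c(4L), fc = c(32L, 16L)),
                     seed = 3)
  rm <- train_with_early_stopping(mlp, sp, cfg)
  expect_true(all(is.finite(rm$history$val_loss)))
  expect_lt(tail(rm$history$train_loss, 1), rm$history$train_loss[1])

  lstm <- build_model("lstm", lstm_config(hidden_size = 8L, fc = 16L),
                      traits = "Narea", seed = 3)
  cfg_l <- train_config(epochs = 4, interval = 2, batch_size = 16, seed = 3,
                        learning_rate = 0.003, shift_rate = 0,
                        spectral_trim = FALSE)
  rl <- train_with_early_stopping(lstm, sp, cfg_l)
  expect_true(all(is.finite(rl$history$val_loss)))
  p <- predict(rl$model, split_part(sp, "test")$x)
  expect_identical(colnames(p), "Narea")
  expect_true(all(is.finite(p)))
})
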