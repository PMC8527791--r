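test_that("masked MSE follows the printed definition", {
  expect_equal(mse_loss(c(1, 3), c(2, 2)), 1.0)
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(mse_loss(c(1, 2), c(1, 2), mask = c(FALSE, FALSE)), "no valid")
  # multi-task: per-trait masked means are summed
  y <- cbind(a = c(1, 3, NA), b = c(2, NA, 4))
  yhat <- cbind(a = c(2, 2, 0), b = c(2, 0, 1))
  expect_equal(mse_loss(y, yhat), mean(c(1, 1)) + mean(c(0, 9)))
})

test_that("evaluation metrics match their definitions at hand-worked points", {
  y <- c(2, 4, 6, 8)
  expect_equal(unname(compute_metrics(y, y)), c(1, 0, 0))
  m <- compute_metrics(y, rep(mean(y), 4))
  expect_equal(unname(m["r2"]), 0)
  expect_equal(unname(compute_metrics(c(0, 1), c(1, 0))["r2"]), -3)
  expect_error(compute_metrics(c(1, 1), c(1, 2)), "variance")
  expect_error(compute_metrics(c(-1, 1), c(0, 0)), "mean")
  expect_error(compute_metrics(1, 1), "at least 2")
})

test_that("metric invariances hold under rescaling", {
  set.seed(8)
  y <- rnorm(50, 10, 2); yhat <- y + rnorm(50, 0, 0.5)
  base <- compute_metrics(y, yhat)
  aff <- compute_metrics(3 * y + 1, 3 * yhat + 1)
  expect_equal(aff[["r2"]], base[["r2"]])
  pos <- compute_metrics(5 * y, 5 * yhat)
  expect_equal(pos[["abs_bias_pct"]], base[["abs_bias_pct"]])
  expect_equal(pos[["rep"]], base[["rep"]])
  expect_equal(pos[["r2"]], base[["r2"]])
})

test_that("early stopping retains the checkpoint with minimal validation loss", {
  sp <- desk_dataset(n = 120, seed = 6)
  m <- build_model("mlp", cnn_config(channels = c(4L, 8L), fc = c(32L, 16L)),
                   seed = 3)
  cfg <- train_config(epochs = 30, interval = 10, batch_size = 16, seed = 3,
                      shift_rate = 0, spectral_trim = FALSE)
  r <- train_with_early_stopping(m, sp, cfg)
  expect_equal(nrow(r$history), 3L)  # <= epochs / interval evaluations
  expect_equal(r$model$best_val_loss, min(r$history$val_loss))
  expect_equal(r$history$val_loss[r$history$epoch == r$model$best_epoch],
               r$model$best_val_loss)

  # recompute the retained checkpoint's validation loss from its weights
  va <- split_part(sp, "validation")
  pred <- predict(r$model, va$x)
  z <- sweep(sweep(va$y, 2, r$model$scaler$mean), 2, r$model$scaler$sd, "/")
  zp <- sweep(sweep(pred, 2, r$model$scaler$mean), 2, r$model$scaler$sd, "/")
  expect_equal(mse_loss(z, zp, va$mask), r$model$best_val_loss,
               tolerance = 1e-10)
})

test_that("training histories are reproducible for a fixed seed", {
  sp <- desk_dataset(n = 100, seed = 7)
  cfg <- train_config(epochs = 10, interval = 10, batch_size = 16, seed = 5)
  mk <- function() build_model("cnn-multi",
                               cnn_config(channels = c(4L, 8L), fc = c(16L, 8L)),
                               seed = 5)
  h1 <- train_with_early_stopping(mk(), sp, cfg)$history
  h2 <- train_with_early_stopping(mk(), sp, cfg)$history
  expect_identical(h1, h2)
})

test_that("PLSR component choice maximises validation R2 (brute-force check)", {
  # latent rank-3 regression problem with little noise
  set.seed(21)
  n <- 90; p <- 40
  scores <- matrix(rnorm(n * 3), n)
  load <- matrix(rnorm(3 * p), 3)
  x <- scores %*% load + matrix(rnorm(n * p, 0, 0.01), n)
  y <- drop(scores %*% c(1, -2, 0.5)) + rnorm(n, 0, 0.01)
  wl <- 400:(400 + p - 1)
  r <- t(x) * 0.01 + 0.5
  colnames(r) <- paste0("s", 1:n)
  ymat <- matrix(NA_real_, n, 10, dimnames = list(NULL, trait_names()))
  ymat[, "LMA"] <- y
  sp <- split_dataset(spectrum_set(wl, r), trait_matrix(paste0("s", 1:n), ymat),
                      seed = 2)
  tuned <- tune_baseline_hyperparams("plsr", sp, traits = "LMA",
                                     range = c(400, 440), max_comp = 10)
  k <- tuned$LMA$ncomp
  expect_gte(k, 1L); expect_lte(k, 30L)

  # independent exhaustive re-evaluation: one separate fit per k
  tr <- split_part(sp, "train"); va <- split_part(sp, "validation")
  ns <- asNamespace("spectratraits")
  r2s <- vapply(1:10, function(kk) {
    f <- ns$plsr_fit_one(tr$x, tr$y[, "LMA"], kk)
    pv <- ns$plsr_predict_one(f, va$x)[, kk]
    1 - sum((va$y[, "LMA"] - pv)^2) / sum((va$y[, "LMA"] - mean(va$y[, "LMA"]))^2)
  }, numeric(1))
  expect_equal(tuned$LMA$val_r2, max(r2s), tolerance = 1e-8)
  expect_equal(k, which.max(r2s))
})

test_that("XGBoost tuning returns a member of the printed grid", {
  sp <- desk_dataset(n = 80, seed = 9)
  tuned <- tune_baseline_hyperparams("xgboost", sp, traits = "LMA",
                                     range = c(400, 430), nrounds = 8)
  g <- spectratraits:::default_xgb_grid()
  expect_true(any(g$eta == tuned$LMA$eta &
                  g$max_depth == tuned$LMA$max_depth &
                  g$colsample_bytree == tuned$LMA$colsample_bytree))
  expect_equal(nrow(g), 6 * 5 * 4)
  expect_setequal(unique(g$eta), c(0.01, 0.02, 0.05, 0.06, 0.08, 0.1))
  expect_setequal(unique(g$max_depth), c(3, 5, 7, 9, 11))
  expect_setequal(unique(g$colsample_bytree), c(0.3, 0.5, 0.8, 1))
})

test_that("component search is capped with a warning on tiny training sets", {
  sp <- desk_dataset(n = 40, seed = 13)
  expect_warning(
    tune_baseline_hyperparams("plsr", sp, traits = "Narea", range = c(400, 600)),
    "capped")
})
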