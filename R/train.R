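#' Training configuration
#'
#' Defaults follow the reference protocol: 1000 epochs of Adam at learning
#' rate 1e-4, validation evaluated every 10 epochs with the best checkpoint
#' retained, offline shift augmentation expanding the training set by 50%,
#' and online spectral trimming for the convolutional models. Batch size is
#' not part of the published protocol; 32 is the package default.
#'
#' @param epochs Training epochs.
#' @param interval Validation interval in epochs; must divide `epochs`.
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed covering shuffling, augmentation, dropout and
#'   weight noise.
#' @param shift_rate Offline shift-augmentation fraction (0 disables).
#' @param spectral_trim Online spectral trimming for CNN-family models.
#' @param trim_dist A [trim_distribution()].
#' @param verbose Print a line per validation evaluation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, interval = 10L, learning_rate = 1e-4,
                         batch_size = 32L, seed = 0L, shift_rate = 0.5,
                         spectral_trim = TRUE,
                         trim_dist = trim_distribution(), verbose = FALSE) {
  if (learning_rate <= 0) stop_validation("learning_rate must be positive")
  if (epochs < 1L || interval < 1L || epochs %% interval != 0L)
    stop_validation("interval must divide epochs")
  structure(list(epochs = as.integer(epochs), interval = as.integer(interval),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 shift_rate = shift_rate, spectral_trim = spectral_trim,
                 trim_dist = trim_dist, verbose = verbose),
            class = "train_config")
}

#' Masked mean squared error
#'
#' For a single trait, the mean of squared errors over valid (masked-in)
#' pairs. For a samples-by-traits matrix, the per-trait masked means are
#' summed — the multi-task loss that keeps traits with few measurements from
#' being swamped, since each observed value enters through its own trait's
#' mean.
#'
#' @param y,yhat Numeric vectors or equally shaped matrices (columns = traits).
#' @param mask Logical, same shape; `TRUE` where the pair is valid. Defaults
#'   to `!is.na(y)`.
#' @return Scalar loss.
#' @export
mse_loss <- function(y, yhat, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(y)
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop_validation("y and yhat must have identical shape")
  if (sum(mask) == 0L) stop_validation("no valid pairs: loss undefined")
  if (is.null(dim(y))) {
    return(mean((y[mask] - yhat[mask])^2))
  }
  per_trait <- vapply(seq_len(ncol(y)), function(j) {
    m <- mask[, j]
    if (!any(m)) return(0)
    mean((y[m, j] - yhat[m, j])^2)
  }, numeric(1))
  sum(per_trait)
}

# Loss + gradient on network output (traits x batch). Per-trait masked mean,
# summed over traits; traits with no valid pair in the batch contribute zero.
masked_mse_grad <- function(out, y, mask) {
  diff <- (out - y) * mask
  nv <- rowSums(mask)
  denom <- pmax(nv, 1)
  loss <- sum(rowSums(diff * diff) / denom)
  grad <- 2 * diff / denom
  list(loss = loss, grad = grad)
}

nn_val_loss <- function(layers, x, ys, mask, batch = 256L) {
  n <- nrow(x)
  total <- 0
  nv <- pmax(colSums(mask), 1)
  for (bi in seq_len(ceiling(n / batch))) {
    idx <- ((bi - 1L) * batch + 1L):min(bi * batch, n)
    arr <- array(t(x[idx, , drop = FALSE]), dim = c(1L, ncol(x), length(idx)))
    out <- nn_forward(layers, arr, training = FALSE)$out
    d <- (out - t(ys[idx, , drop = FALSE])) * t(mask[idx, , drop = FALSE])
    total <- total + rowSums(d * d)
  }
  sum(total / nv)
}

#' Train a neural model with early stopping
#'
#' Trains for `cfg$epochs` epochs of mini-batch Adam on the masked multi-task
#' MSE over z-scored targets (per-trait statistics from the training
#' partition). Every `cfg$interval` epochs the validation loss is recorded
#' and the best-scoring weights are retained; training always runs to the
#' epoch budget and the checkpoint with the lowest validation loss is
#' returned, which in practice is found well before the end.
#'
#' Augmentation follows the configuration: the training partition is first
#' expanded offline with shift-augmented copies (`cfg$shift_rate`), and for
#' convolutional kinds each mini-batch presentation independently re-samples
#' spectral-trimming bounds (`cfg$spectral_trim`), so the trimming is online.
#' Deterministic given `cfg$seed` and a fixed BLAS thread count.
#'
#' @param model An untrained neural `trait_model` from [build_model()].
#' @param data A [split_dataset()] with non-empty train and validation
#'   partitions.
#' @param cfg A [train_config()].
#' @return List with `model` (best checkpoint, ready for `predict()`) and
#'   `history` (data frame of epoch, training loss, validation loss).
#' @export
train_with_early_stopping <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "trait_model"), inherits(data, "split_dataset"),
            inherits(cfg, "train_config"))
  if (!model$kind %in% c("cnn-multi", "cnn-single", "mlp", "lstm"))
    stop_validation("train_with_early_stopping handles neural kinds; use fit_",
                    model$kind, "() instead")
  tr <- split_part(data, "train"); va <- split_part(data, "validation")
  if (nrow(tr$x) == 0L || nrow(va$x) == 0L)
    stop_validation("train and validation partitions must be non-empty")
  set.seed(cfg$seed)
  if (cfg$shift_rate > 0)
    tr <- expand_training_set(tr, cfg$shift_rate, seed = cfg$seed)
  traits <- model$traits
  ytr <- tr$y[, traits, drop = FALSE]; mtr <- tr$mask[, traits, drop = FALSE]
  yva <- va$y[, traits, drop = FALSE]; mva <- va$mask[, traits, drop = FALSE]
  keep <- rowSums(mtr) > 0L
  xtr <- conform_input(tr$x[keep, , drop = FALSE], model$wavelengths)
  ytr <- ytr[keep, , drop = FALSE]; mtr <- mtr[keep, , drop = FALSE]
  xva <- conform_input(va$x, model$wavelengths)
  mu <- vapply(seq_along(traits), function(j) mean(ytr[mtr[, j], j]), numeric(1))
  sd_ <- vapply(seq_along(traits), function(j) stats::sd(ytr[mtr[, j], j]), numeric(1))
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  scaler <- list(mean = stats::setNames(mu, traits), sd = stats::setNames(sd_, traits))
  zs <- function(y, m) { z <- sweep(sweep(y, 2L, mu, `-`), 2L, sd_, `/`); z[!m] <- 0; z }
  ztr <- zs(ytr, mtr); zva <- zs(yva, mva)

  layers <- model$net
  state <- adam_init(layers)
  n <- nrow(xtr)
  use_trim <- cfg$spectral_trim && model$kind %in% c("cnn-multi", "cnn-single")
  n_eval <- cfg$epochs %/% cfg$interval
  history <- data.frame(epoch = integer(n_eval), train_loss = numeric(n_eval),
                        val_loss = numeric(n_eval))
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  step <- 0L
  wl <- model$wavelengths
  hrow <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0; nb <- 0L
    for (bs in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[bs:min(bs + cfg$batch_size - 1L, n)]
      xb <- xtr[idx, , drop = FALSE]
      if (use_trim) {
        bounds <- sample_trim_bounds(cfg$trim_dist, length(idx))
        xb <- apply_spectral_trim_rows(xb, wl, bounds)
      }
      arr <- array(t(xb), dim = c(1L, ncol(xb), length(idx)))
      fw <- nn_forward(layers, arr, training = TRUE)
      layers <- fw$layers
      lg <- masked_mse_grad(fw$out, t(ztr[idx, , drop = FALSE]),
                            t(mtr[idx, , drop = FALSE]))
      if (!is.finite(lg$loss))
        stop("training diverged at epoch ", epoch, " (non-finite loss); ",
             "lower the learning rate or check the inputs")
      bw <- nn_backward(layers, fw$caches, lg$grad)
      step <- step + 1L
      up <- adam_update(layers, bw$grads, state, cfg$learning_rate, step)
      layers <- up$layers; state <- up$state
      epoch_loss <- epoch_loss + lg$loss; nb <- nb + 1L
    }
    if (epoch %% cfg$interval == 0L) {
      vloss <- nn_val_loss(layers, xva, zva, mva)
      hrow <- hrow + 1L
      history[hrow, ] <- list(epoch, epoch_loss / nb, vloss)
      if (cfg$verbose)
        message(sprintf("epoch %d: train %.5f val %.5f", epoch,
                        epoch_loss / nb, vloss))
      if (vloss < best$loss)
        best <- list(loss = vloss, layers = layers, epoch = epoch)
    }
  }
  model$net <- best$layers
  model$scaler <- scaler
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$loss
  list(model = model, history = history)
}
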