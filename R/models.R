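#' Dilated 1D convolutional layer specification
#'
#' Describes (and optionally carries the weights of) one dilated 1D
#' convolution: output channel \eqn{c_o} of layer \eqn{l} is
#' \eqn{f(\sum_{c_i} W^{(l),c_i}_{c_o} \ast X^{(l-1),c_i} + B^l_{c_o})}, a
#' dilated cross-correlation over input channels plus a per-channel bias,
#' optionally batch-normalised before the activation \eqn{f}.
#'
#' @param in_channels,out_channels Channel counts.
#' @param filter_size Odd kernel width (default 5).
#' @param dilation Spacing between kernel taps (default 2).
#' @param weights Optional array `(out_channels, in_channels, filter_size)`;
#'   He-initialised when omitted.
#' @param bias Optional numeric vector of length `out_channels`.
#' @param activation `"relu"` or `"identity"`.
#' @param batchnorm Normalise the pre-activation per output channel using
#'   batch statistics (unit gain, zero shift).
#' @return An object of class `conv_layer_spec`.
#' @export
conv_layer_spec <- function(in_channels, out_channels, filter_size = 5L,
                            dilation = 2L, weights = NULL, bias = NULL,
                            activation = c("relu", "identity"),
                            batchnorm = FALSE) {
  activation <- match.arg(activation)
  l <- layer_conv1d(in_channels, out_channels, filter_size, dilation)
  if (!is.null(weights)) {
    if (!identical(dim(weights), as.integer(c(out_channels, in_channels, filter_size))))
      stop_validation("weights must have dim (out_channels, in_channels, filter_size)")
    l$params$W <- weights
  }
  if (!is.null(bias)) {
    if (length(bias) != out_channels)
      stop_validation("bias must have length out_channels")
    l$params$b <- bias
  }
  structure(c(l, list(activation = activation, batchnorm = batchnorm)),
            class = "conv_layer_spec")
}

#' Apply a dilated 1D convolution
#'
#' Runs one [conv_layer_spec()] over a `channels x length` input with "same"
#' zero padding and stride 1, so the output keeps the input length — the
#' convention that lets zero-filled trimmed spectra pass through unchanged in
#' shape.
#'
#' @param x Numeric matrix `in_channels x length` (a plain vector is treated
#'   as one channel).
#' @param layer A [conv_layer_spec()].
#' @return Numeric matrix `out_channels x length`.
#' @export
dilated_conv1d <- function(x, layer) {
  stopifnot(inherits(layer, "conv_layer_spec"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) != layer$in_ch)
    stop_validation("input has ", nrow(x), " channels but the layer expects ",
                    layer$in_ch)
  arr <- array(x, dim = c(nrow(x), ncol(x), 1L))
  out <- forward_layer(unclass(layer), arr)$out
  out <- matrix(out, layer$out_ch, ncol(x))
  if (isTRUE(layer$batchnorm)) {
    mu <- rowMeans(out)
    s <- sqrt(rowMeans((out - mu)^2) + 1e-5)
    out <- (out - mu) / s
  }
  if (layer$activation == "relu") out[out < 0] <- 0
  out
}

#' Receptive field of a stride-1 dilated convolution stack
#'
#' Number of input elements that influence a single output neuron:
#' `1 + sum((filter_size - 1) * dilation)` over the layers. For two layers of
#' filter size 5 with dilations 1 and 2 this is 13.
#'
#' @param filter_sizes,dilations,strides Equal-length integer vectors; only
#'   stride 1 is supported.
#' @return Integer receptive-field size.
#' @export
#' @examples
#' receptive_field(c(5, 5), c(1, 2))  # 13
receptive_field <- function(filter_sizes, dilations,
                            strides = rep(1L, length(filter_sizes))) {
  if (length(filter_sizes) == 0L)
    stop_validation("at least one layer is required")
  if (length(dilations) != length(filter_sizes) ||
      length(strides) != length(filter_sizes))
    stop_validation("filter_sizes, dilations and strides must have equal length")
  if (any(strides != 1L))
    stop_validation("only stride-1 stacks are supported")
  as.integer(1L + sum((filter_sizes - 1L) * dilations))
}

#' Convolutional network configuration
#'
#' The default reproduces the reference architecture: average pool 10, four
#' dilated conv layers (filter 5, dilation 2, batch norm + ReLU) with 75, 150,
#' 225 and 300 filters, then fully connected layers of 800 and 200 units with
#' ReLU and dropout 0.2, and a final linear layer of 10 (multi-task) or 1
#' (single-task) outputs. `preset = "desk"` selects a narrower stack
#' (12/24/36/48 channels, FC 128/64) with the identical layer sequence, sized
#' for CPU-scale training; see the methods vignette.
#'
#' @param output_size 10 (multi-task) or 1 (single-task).
#' @param channels Filters per conv layer.
#' @param fc Hidden fully connected sizes.
#' @param pool_window,filter_size,dilation,dropout,input_length Remaining
#'   architecture constants.
#' @param preset `"default"` or `"desk"`.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(output_size = 10L,
                       channels = c(75L, 150L, 225L, 300L),
                       fc = c(800L, 200L),
                       pool_window = 10L, filter_size = 5L, dilation = 2L,
                       dropout = 0.2, input_length = 2000L,
                       preset = c("default", "desk")) {
  preset <- match.arg(preset)
  if (preset == "desk" && missing(channels) && missing(fc)) {
    channels <- c(12L, 24L, 36L, 48L)
    fc <- c(128L, 64L)
  }
  if (!output_size %in% c(1L, 10L))
    stop_validation("output_size must be 1 or 10")
  if (dropout < 0 || dropout >= 1) stop_validation("dropout must be in [0, 1)")
  if (input_length %% pool_window != 0L)
    stop_validation("input_length must be divisible by pool_window")
  structure(list(output_size = as.integer(output_size), channels = channels,
                 fc = fc, pool_window = pool_window, filter_size = filter_size,
                 dilation = dilation, dropout = dropout,
                 input_length = as.integer(input_length), preset = preset),
            class = "cnn_config")
}

#' LSTM network configuration
#'
#' Two stacked bidirectional recurrent layers with 100-dimensional hidden
#' units over the pooled spectrum, a 200-unit fully connected layer with ReLU,
#' and a single-trait linear output.
#'
#' @param hidden_size Hidden units per direction.
#' @param num_layers Stacked bidirectional layers.
#' @param fc Fully connected layer size.
#' @param pool_window,input_length As in [cnn_config()].
#' @return An object of class `lstm_config`.
#' @export
lstm_config <- function(hidden_size = 100L, num_layers = 2L, fc = 200L,
                        pool_window = 10L, input_length = 2000L) {
  structure(list(hidden_size = as.integer(hidden_size),
                 num_layers = as.integer(num_layers), fc = as.integer(fc),
                 pool_window = pool_window,
                 input_length = as.integer(input_length)),
            class = "lstm_config")
}

model_kinds <- function() {
  c("cnn-multi", "cnn-single", "mlp", "lstm", "plsr", "xgboost", "ensemble")
}

#' Build an (untrained) predictor
#'
#' Assembles the layer stack for the neural kinds (`cnn-multi`, `cnn-single`,
#' `mlp`, `lstm`) or an unfitted wrapper for the classical baselines (`plsr`,
#' `xgboost`). Neural models are trained with [train_with_early_stopping()];
#' baselines with [fit_plsr()] / [fit_xgboost()].
#'
#' @param kind One of `"cnn-multi"`, `"cnn-single"`, `"mlp"`, `"lstm"`,
#'   `"plsr"`, `"xgboost"`.
#' @param config A [cnn_config()] or [lstm_config()] where applicable; the
#'   kind's default when omitted.
#' @param traits Trait names the model predicts (all ten by default;
#'   single-output kinds take exactly one).
#' @param seed Optional integer seed for weight initialisation.
#' @return An object of class `trait_model`.
#' @export
build_model <- function(kind, config = NULL, traits = trait_names(),
                        seed = NULL) {
  if (!kind %in% setdiff(model_kinds(), "ensemble"))
    stop_validation("unknown model kind: ", kind)
  if (!is.null(seed)) set.seed(seed)
  single_out <- kind %in% c("cnn-single", "lstm")
  if (single_out && length(traits) != 1L)
    stop_validation(kind, " predicts a single trait; pass exactly one trait name")
  net <- NULL
  if (kind %in% c("cnn-multi", "cnn-single")) {
    if (is.null(config))
      config <- cnn_config(output_size = if (single_out) 1L else 10L)
    if (kind == "cnn-multi" && config$output_size != length(traits))
      stop_validation("config output_size (", config$output_size,
                      ") does not match number of traits (", length(traits), ")")
    if (kind == "cnn-single" && config$output_size != 1L)
      stop_validation("cnn-single requires output_size 1")
    net <- build_cnn_layers(config)
  } else if (kind == "mlp") {
    if (is.null(config)) config <- cnn_config(output_size = length(traits))
    net <- build_mlp_layers(config)
  } else if (kind == "lstm") {
    if (is.null(config)) config <- lstm_config()
    net <- build_lstm_layers(config)
  }
  input_length <- if (!is.null(config$input_length)) config$input_length else 2000L
  structure(list(kind = kind, config = config, net = net, fit = NULL,
                 traits = traits, scaler = NULL,
                 wavelengths = seq(400L, length.out = input_length),
                 range = c(400L, 400L + input_length)),
            class = "trait_model")
}

build_cnn_layers <- function(cfg) {
  layers <- list(layer_avgpool(cfg$pool_window))
  in_ch <- 1L
  for (ch in cfg$channels) {
    layers <- c(layers, list(layer_conv1d(in_ch, ch, cfg$filter_size, cfg$dilation),
                             layer_batchnorm(ch), layer_relu()))
    in_ch <- ch
  }
  flat <- in_ch * (cfg$input_length %/% cfg$pool_window)
  layers <- c(layers, list(layer_flatten()))
  in_dim <- flat
  for (h in cfg$fc) {
    layers <- c(layers, list(layer_dense(in_dim, h), layer_relu(),
                             layer_dropout(cfg$dropout)))
    in_dim <- h
  }
  c(layers, list(layer_dense(in_dim, cfg$output_size)))
}

build_mlp_layers <- function(cfg) {
  layers <- list(layer_avgpool(cfg$pool_window), layer_flatten())
  in_dim <- cfg$input_length %/% cfg$pool_window
  for (h in cfg$fc) {
    layers <- c(layers, list(layer_dense(in_dim, h), layer_relu(),
                             layer_dropout(cfg$dropout)))
    in_dim <- h
  }
  c(layers, list(layer_dense(in_dim, cfg$output_size)))
}

build_lstm_layers <- function(cfg) {
  layers <- list(layer_avgpool(cfg$pool_window))
  in_size <- 1L
  for (l in seq_len(cfg$num_layers)) {
    layers <- c(layers, list(layer_bilstm(in_size, cfg$hidden_size)))
    in_size <- 2L * cfg$hidden_size
  }
  c(layers, list(layer_last_concat(cfg$hidden_size),
                 layer_dense(2L * cfg$hidden_size, cfg$fc), layer_relu(),
                 layer_dense(cfg$fc, 1L)))
}

#' @export
print.trait_model <- function(x, ...) {
  cat("<trait_model> kind=", x$kind, ", traits: ",
      paste(x$traits, collapse = ", "),
      if (is.null(x$net) && is.null(x$fit)) " (unfitted)" else "", "\n", sep = "")
  if (!is.null(x$net)) cat("  ", nn_count_params(x$net), " learnable parameters\n", sep = "")
  invisible(x)
}

# Conform arbitrary input (spectrum_set or samples x wavelengths matrix) to a
# model's fixed grid: values on covered wavelengths are copied, uncovered
# positions stay zero — the same convention the spectral-trimming augmentation
# trains the networks to tolerate.
conform_input <- function(newdata, wavelengths, require_full = FALSE) {
  if (inherits(newdata, "spectrum_set")) {
    x <- t(newdata$reflectance)
    colnames(x) <- newdata$wavelengths
  } else {
    x <- as.matrix(newdata)
    if (is.null(colnames(x))) {
      if (ncol(x) != length(wavelengths))
        stop_validation("matrix input must have ", length(wavelengths),
                        " columns or wavelength column names")
      colnames(x) <- wavelengths
    }
  }
  out <- matrix(0, nrow(x), length(wavelengths),
                dimnames = list(rownames(x), wavelengths))
  shared <- intersect(colnames(x), as.character(wavelengths))
  if (length(shared) == 0L) stop_validation("input covers none of the model grid")
  if (require_full && length(shared) < length(wavelengths))
    stop_validation("input must cover the model's full wavelength range ",
                    min(wavelengths), "-", max(wavelengths), " nm")
  out[, shared] <- x[, shared]
  out
}

nn_predict_matrix <- function(object, x, batch = 256L) {
  n <- nrow(x)
  outs <- vector("list", ceiling(n / batch))
  for (bi in seq_along(outs)) {
    idx <- ((bi - 1L) * batch + 1L):min(bi * batch, n)
    arr <- array(t(x[idx, , drop = FALSE]), dim = c(1L, ncol(x), length(idx)))
    outs[[bi]] <- t(nn_forward(object$net, arr, training = FALSE)$out)
  }
  do.call(rbind, outs)
}

#' Predict traits from spectra
#'
#' Conforms the input to the model's 400–2399 nm grid (uncovered wavelengths
#' zero-filled), runs the fitted model in inference mode (dropout off, batch
#' norm on running statistics) and returns predictions in original trait
#' units.
#'
#' @param object A fitted [build_model()] / [fit_plsr()] / [fit_xgboost()]
#'   model.
#' @param newdata A [spectrum_set()] or samples-by-wavelength matrix.
#' @param ... Unused.
#' @return Numeric matrix, one row per observation, one column per trait.
#' @export
predict.trait_model <- function(object, newdata, ...) {
  x <- conform_input(newdata, object$wavelengths,
                     require_full = object$kind %in% c("plsr", "xgboost"))
  if (object$kind %in% c("cnn-multi", "cnn-single", "mlp", "lstm")) {
    if (is.null(object$scaler))
      stop_validation("model has not been trained; see train_with_early_stopping()")
    p <- nn_predict_matrix(object, x)
    p <- sweep(sweep(p, 2L, object$scaler$sd, `*`), 2L, object$scaler$mean, `+`)
  } else if (object$kind == "plsr") {
    p <- predict_plsr_fit(object, x)
  } else if (object$kind == "xgboost") {
    p <- predict_xgboost_fit(object, x)
  } else {
    stop_validation("cannot predict with kind ", object$kind)
  }
  colnames(p) <- object$traits
  rownames(p) <- rownames(x)
  p
}

#' Average an ensemble of trait predictors
#'
#' Returns the arithmetic mean of the member predictions, per observation and
#' per trait — the ensemble rule used by the reference models, whose default
#' membership is the spectrally-trimmed multi-task CNN, the spectrally-trimmed
#' single-task CNNs and PLSR.
#'
#' @param members Non-empty list of fitted models (anything with a `predict`
#'   method returning an observations-by-traits matrix).
#' @param s A [spectrum_set()] or samples-by-wavelength matrix.
#' @param traits Traits to predict; defaults to those of the first member.
#' @return Numeric matrix of mean predictions.
#' @export
ensemble_predict <- function(members, s, traits = NULL) {
  if (length(members) == 0L) stop_validation("ensemble needs at least one member")
  preds <- lapply(members, function(m) stats::predict(m, s))
  if (is.null(traits)) traits <- colnames(preds[[1L]])
  for (p in preds)
    if (!all(traits %in% colnames(p)))
      stop_validation("every member must predict all requested traits")
  acc <- Reduce(`+`, lapply(preds, function(p) p[, traits, drop = FALSE]))
  acc / length(members)
}

#' Choose the best-fitting fixed PLSR range
#'
#' The fixed-range PLSR variants are trained on \[400, 900\], \[400, 1000\],
#' \[400, 1700\] and \[400, 2400\] nm. Returns the largest of these fully
#' contained in the input's coverage; inputs are trimmed to that range before
#' PLSR prediction.
#'
#' @param s A [spectrum_set()].
#' @return Numeric vector `c(low, high)` of the matched range.
#' @export
match_plsr_range <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  lo <- min(s$wavelengths); hi <- max(s$wavelengths)
  uppers <- c(2400, 1700, 1000, 900)
  for (u in uppers) {
    if (lo <= 400 && hi >= u - 1) return(c(400, u))
  }
  stop_validation("spectrum coverage ", lo, "-", hi,
                  " nm is narrower than the minimum supported range [400, 900]")
}
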