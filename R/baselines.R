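# Classical baselines. PLSR is the field's standard chemometrics model and is
# delegated to mixOmics (NIPALS, mode = "regression"); XGBoost to the xgboost
# package. Both are fitted per trait on the raw per-nm reflectance of a fixed
# wavelength range, with hyperparameters chosen on the validation partition.

plsr_ranges <- function() list(c(400, 900), c(400, 1000), c(400, 1700), c(400, 2400))

default_xgb_grid <- function() {
  expand.grid(max_depth = c(3L, 5L, 7L, 9L, 11L),
              eta = c(0.01, 0.02, 0.05, 0.06, 0.08, 0.1),
              colsample_bytree = c(0.3, 0.5, 0.8, 1))[, c("eta", "max_depth", "colsample_bytree")]
}

range_columns <- function(wavelengths, range) {
  wavelengths >= range[1L] & wavelengths < range[2L]
}

valid_xy <- function(part, trait, cols) {
  ok <- part$mask[, trait]
  list(x = part$x[ok, cols, drop = FALSE], y = part$y[ok, trait])
}

#' Tune baseline hyperparameters on the validation partition
#'
#' PLSR: the number of latent components is searched over 1..`max_comp`
#' (default 30) and the value maximising validation R-squared is kept, ties
#' resolved toward fewer components. XGBoost: `(eta, max_depth,
#' colsample_bytree)` are searched over the fixed grid
#' (0.01, 0.02, 0.05, 0.06, 0.08, 0.1) x (3, 5, 7, 9, 11) x (0.3, 0.5, 0.8, 1),
#' again maximising validation R-squared with ties toward shallower trees.
#'
#' @param kind `"plsr"` or `"xgboost"`.
#' @param data A [split_dataset()].
#' @param traits Traits to tune (default all ten).
#' @param range Wavelength window `c(low, high)`, half-open, used as features.
#' @param max_comp PLSR search upper bound.
#' @param grid XGBoost search grid (data frame with columns `eta`,
#'   `max_depth`, `colsample_bytree`).
#' @param nrounds Boosting rounds per XGBoost fit.
#' @return Named list, one entry per trait: `list(ncomp=)` for PLSR or
#'   `list(eta=, max_depth=, colsample_bytree=)` for XGBoost, each with the
#'   achieved `val_r2`.
#' @export
tune_baseline_hyperparams <- function(kind = c("plsr", "xgboost"), data,
                                      traits = trait_names(),
                                      range = c(400, 2400), max_comp = 30L,
                                      grid = default_xgb_grid(),
                                      nrounds = 100L) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "split_dataset"))
  tr <- split_part(data, "train"); va <- split_part(data, "validation")
  cols <- range_columns(data$wavelengths, range)
  out <- list()
  for (trait in traits) {
    dtr <- valid_xy(tr, trait, cols); dva <- valid_xy(va, trait, cols)
    if (nrow(dva$x) < 2L)
      stop_validation("validation partition holds fewer than 2 observed values for ", trait)
    if (kind == "plsr") {
      kmax <- min(max_comp, nrow(dtr$x) - 1L, ncol(dtr$x))
      if (kmax < max_comp)
        warning("component search for ", trait, " capped at ", kmax,
                " (limited training samples)", call. = FALSE)
      fit <- plsr_fit_one(dtr$x, dtr$y, kmax)
      pv <- plsr_predict_one(fit, dva$x)     # n_val x kmax
      r2 <- apply(pv, 2L, function(p) r_squared(dva$y, p))
      k <- which.max(r2)
      out[[trait]] <- list(ncomp = as.integer(k), val_r2 = r2[k])
    } else {
      best <- NULL
      ord <- order(grid$max_depth, grid$eta)   # simpler models first; ties -> simpler
      for (gi in ord) {
        fit <- xgb_fit_one(dtr$x, dtr$y, grid$eta[gi], grid$max_depth[gi],
                           grid$colsample_bytree[gi], nrounds)
        r2 <- r_squared(dva$y, stats::predict(fit, dva$x))
        if (is.null(best) || r2 > best$val_r2)
          best <- list(eta = grid$eta[gi], max_depth = grid$max_depth[gi],
                       colsample_bytree = grid$colsample_bytree[gi], val_r2 = r2)
      }
      out[[trait]] <- best
    }
  }
  out
}

plsr_fit_one <- function(x, y, ncomp) {
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  mixOmics::pls(x, matrix(y, dimnames = list(NULL, "y")), ncomp = ncomp,
                mode = "regression")
}

plsr_predict_one <- function(fit, x) {
  # ensure mixOmics' S3 predict method is registered in fresh sessions that
  # only deserialised a fitted model
  requireNamespace("mixOmics", quietly = TRUE)
  colnames(x) <- paste0("w", seq_len(ncol(x)))
  p <- stats::predict(fit, x)$predict
  matrix(p[, 1L, ], nrow(x))
}

xgb_fit_one <- function(x, y, eta, max_depth, colsample_bytree, nrounds) {
  d <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = list(eta = eta, max_depth = max_depth,
                                   colsample_bytree = colsample_bytree,
                                   objective = "reg:squarederror",
                                   nthread = 1L, seed = 0L),
                     data = d, nrounds = nrounds, verbose = 0L)
}

#' Fit per-trait PLSR models
#'
#' One PLSR model per trait on the raw reflectance of a fixed wavelength
#' range, components tuned on the validation partition unless `ncomp` is
#' given.
#'
#' @param data A [split_dataset()].
#' @param traits Traits to fit.
#' @param range Half-open wavelength window used as features.
#' @param ncomp Optional named list/vector of per-trait component counts;
#'   tuned via [tune_baseline_hyperparams()] when `NULL`.
#' @param max_comp Search upper bound when tuning.
#' @return A fitted `trait_model` of kind `"plsr"`.
#' @export
fit_plsr <- function(data, traits = trait_names(), range = c(400, 2400),
                     ncomp = NULL, max_comp = 30L) {
  stopifnot(inherits(data, "split_dataset"))
  cols <- range_columns(data$wavelengths, range)
  if (!any(cols)) stop_validation("range covers no wavelengths of the data")
  tuned <- NULL
  if (is.null(ncomp)) {
    tuned <- tune_baseline_hyperparams("plsr", data, traits, range, max_comp)
    ncomp <- lapply(tuned, `[[`, "ncomp")
  }
  tr <- split_part(data, "train")
  fits <- list()
  for (trait in traits) {
    d <- valid_xy(tr, trait, cols)
    k <- as.integer(ncomp[[trait]])
    if (is.na(k) || k < 1L || k > 30L)
      stop_validation("ncomp for ", trait, " must be in [1, 30]")
    fits[[trait]] <- list(fit = plsr_fit_one(d$x, d$y, k), ncomp = k)
  }
  structure(list(kind = "plsr", config = list(range = range, tuned = tuned),
                 net = NULL, fit = fits, traits = traits, scaler = NULL,
                 wavelengths = data$wavelengths[cols], range = range),
            class = "trait_model")
}

predict_plsr_fit <- function(object, x) {
  # x arrives conformed to the model grid; coverage was enforced upstream
  # (fixed-range PLSR does not accept zero-filled gaps).
  vapply(object$traits, function(trait) {
    f <- object$fit[[trait]]
    plsr_predict_one(f$fit, x)[, f$ncomp]
  }, numeric(nrow(x)))
}

#' Fit per-trait XGBoost models
#'
#' @inheritParams fit_plsr
#' @param params Optional named list of per-trait lists
#'   `(eta, max_depth, colsample_bytree)`; tuned on the validation partition
#'   when `NULL`.
#' @param grid Search grid passed to [tune_baseline_hyperparams()].
#' @param nrounds Boosting rounds.
#' @return A fitted `trait_model` of kind `"xgboost"`.
#' @export
fit_xgboost <- function(data, traits = trait_names(), range = c(400, 2400),
                        params = NULL, grid = default_xgb_grid(),
                        nrounds = 100L) {
  stopifnot(inherits(data, "split_dataset"))
  cols <- range_columns(data$wavelengths, range)
  tuned <- NULL
  if (is.null(params)) {
    tuned <- tune_baseline_hyperparams("xgboost", data, traits, range,
                                       grid = grid, nrounds = nrounds)
    params <- tuned
  }
  tr <- split_part(data, "train")
  fits <- list()
  for (trait in traits) {
    d <- valid_xy(tr, trait, cols)
    p <- params[[trait]]
    fits[[trait]] <- xgb_fit_one(d$x, d$y, p$eta, p$max_depth,
                                 p$colsample_bytree, nrounds)
  }
  structure(list(kind = "xgboost", config = list(range = range, tuned = tuned,
                                                 nrounds = nrounds),
                 net = NULL, fit = fits, traits = traits, scaler = NULL,
                 wavelengths = data$wavelengths[cols], range = range),
            class = "trait_model")
}

predict_xgboost_fit <- function(object, x) {
  requireNamespace("xgboost", quietly = TRUE)
  vapply(object$traits, function(trait) {
    stats::predict(object$fit[[trait]], x)
  }, numeric(nrow(x)))
}

#' Fit a family of fixed-range PLSR models
#'
#' One [fit_plsr()] model per supported range (\[400,900\], \[400,1000\],
#' \[400,1700\], \[400,2400\]); at prediction time [match_plsr_range()] picks
#' the largest range covered by the input.
#'
#' @inheritParams fit_plsr
#' @return Named list of fitted `trait_model`s keyed `"400-900"` etc.
#' @export
fit_plsr_ranges <- function(data, traits = trait_names(), max_comp = 30L) {
  fits <- lapply(plsr_ranges(), function(r)
    fit_plsr(data, traits, range = r, max_comp = max_comp))
  names(fits) <- vapply(plsr_ranges(), function(r) paste(r, collapse = "-"), "")
  fits
}
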