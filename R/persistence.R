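model_config_hash <- function(model) {
  desc <- list(kind = model$kind, config = model$config, traits = model$traits,
               wavelengths = range(model$wavelengths))
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(desc, tf)
  unname(tools::md5sum(tf))
}

#' Save a fitted model archive
#'
#' Writes a self-describing archive (kind, architecture configuration,
#' weights/fits, target-scaling statistics, training-range metadata) plus a
#' hash of the configuration so [load_model()] can reject archives that do
#' not match what this package's builders produce.
#'
#' @param model A `trait_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trait_model"))
  saveRDS(list(format = "spectratraits-model-1", model = model,
               config_hash = model_config_hash(model)), path)
  invisible(path)
}

#' Load a fitted model archive
#'
#' @param path Path written by [save_model()].
#' @return The stored `trait_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "spectratraits-model-1"))
    stop_validation("not a spectratraits model archive: ", path)
  if (!identical(obj$config_hash, model_config_hash(obj$model)))
    stop_validation("model archive configuration hash mismatch: ", path,
                    " was not produced by this package's builders")
  obj$model
}
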