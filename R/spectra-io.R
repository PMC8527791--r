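#' Construct a spectrum set
#'
#' A `spectrum_set` couples an integer wavelength grid in strict 1 nm steps
#' with one reflectance vector per named observation. Reflectance is unitless
#' and nominally in \[0, 1\]; values slightly outside that range are accepted
#' with a warning since real instruments can exceed 1 near specular angles.
#'
#' @param wavelengths Integer-valued vector of wavelengths (nm), strictly
#'   increasing in steps of exactly 1.
#' @param reflectance Numeric matrix, one row per wavelength and one column per
#'   observation; column names are the observation names and must be unique.
#' @param provenance Free-text source tag stored with the object.
#' @return An object of class `spectrum_set`.
#' @export
#' @examples
#' wl <- 400:409
#' r <- matrix(runif(20, 0.2, 0.5), nrow = 10, dimnames = list(NULL, c("a", "b")))
#' spectrum_set(wl, r)
spectrum_set <- function(wavelengths, reflectance, provenance = "unknown") {
  if (!is.numeric(wavelengths) || length(wavelengths) < 2L)
    stop_schema("wavelengths must be a numeric vector of length >= 2")
  if (any(wavelengths != round(wavelengths)))
    stop_schema("wavelengths must be whole numbers of nm")
  d <- diff(wavelengths)
  if (any(d != 1))
    stop_schema("wavelength grid must increase in steps of exactly 1 nm; ",
                "offending step at position ", which(d != 1)[1L])
  if (is.null(dim(reflectance))) reflectance <- matrix(reflectance, ncol = 1L)
  if (nrow(reflectance) != length(wavelengths))
    stop_schema("reflectance has ", nrow(reflectance), " rows but the grid has ",
                length(wavelengths), " wavelengths")
  nm <- colnames(reflectance)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop_schema("every observation (column) must be named")
  if (anyDuplicated(nm))
    stop_schema("duplicate observation names: ",
                paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (anyNA(reflectance))
    stop_schema("reflectance contains missing values")
  out_of_band <- sum(reflectance < 0 | reflectance > 1)
  if (out_of_band > 0L)
    warning(out_of_band, " reflectance value(s) outside [0, 1]", call. = FALSE)
  structure(list(wavelengths = as.integer(wavelengths),
                 reflectance = reflectance,
                 provenance = provenance),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", ncol(x$reflectance), " observation(s), grid ",
      min(x$wavelengths), "-", max(x$wavelengths), " nm (",
      length(x$wavelengths), " points), source: ", x$provenance, "\n", sep = "")
  invisible(x)
}

n_observations <- function(s) ncol(s$reflectance)

#' Read a spectra CSV file
#'
#' Expected schema: the first column holds numeric wavelengths in 1 nm
#' increments; the header row names each observation; each remaining column is
#' one observation's reflectance. At most `max_observations` observations are
#' kept — extra columns are dropped with a warning, mirroring the resource cap
#' of shared prediction services.
#'
#' @param path Path to a CSV file.
#' @param max_observations Cap on the number of observations read (default 100).
#' @return A [spectrum_set()].
#' @export
read_spectra_csv <- function(path, max_observations = 100L) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  assert_scalar_number(max_observations, "max_observations")
  if (max_observations < 1) stop_validation("max_observations must be >= 1")
  hdr <- as.character(unlist(utils::read.csv(path, check.names = FALSE,
                                             header = FALSE, nrows = 1L,
                                             stringsAsFactors = FALSE)))
  if (length(hdr) >= 2L && anyDuplicated(hdr[-1L]))
    stop_schema("duplicate observation names in header: ",
                paste(unique(hdr[-1L][duplicated(hdr[-1L])]), collapse = ", "))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop_schema("spectra CSV must contain a wavelength column plus at least ",
                "one observation column; got ", ncol(df), " column(s)")
  colnames(df) <- hdr
  wl <- suppressWarnings(as.numeric(df[[1L]]))
  if (anyNA(wl))
    stop_schema("first column must be numeric wavelengths; row ",
                which(is.na(wl))[1L], " of column 1 does not parse")
  obs <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(obs))
    stop_schema("reflectance columns must be numeric")
  if (ncol(obs) > max_observations) {
    warning("file holds ", ncol(obs), " observations; only the first ",
            max_observations, " are processed", call. = FALSE)
    obs <- obs[, seq_len(max_observations), drop = FALSE]
  }
  spectrum_set(wl, obs, provenance = path)
}

#' Write a spectra CSV file
#'
#' Inverse of [read_spectra_csv()]: wavelengths in the first column, one named
#' column per observation, plain UTF-8 CSV with '.' decimal separator.
#'
#' @param s A [spectrum_set()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  df <- data.frame(wavelength = s$wavelengths, check.names = FALSE)
  df <- cbind(df, as.data.frame(s$reflectance, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Correct detector splice discontinuities ("jump correction")
#'
#' Multi-detector spectroradiometers produce step discontinuities at the
#' wavelengths where one detector hands over to the next (typically 1000 and
#' 1800 or 1830 nm). For each jump wavelength `j`, processed left to right, the
#' whole segment to the right of `j` is shifted by a constant so that the first
#' difference across the splice equals the mean first difference of the five
#' points on each side of `j`. The offset is additive because the artifact is a
#' detector offset, not a gain change. All other first differences — and hence
#' the spectral shape away from the splice — are untouched, and the operation
#' is idempotent.
#'
#' @param s A [spectrum_set()].
#' @param jump_wavelengths Integer nm positions of the splices, each within
#'   \[355, 2495\] and inside the spectrum's grid (default `c(1000, 1800)`).
#' @param method Offset model; only `"additive"` is implemented.
#' @return A corrected [spectrum_set()] on the identical grid.
#' @export
jump_correct <- function(s, jump_wavelengths = c(1000L, 1800L),
                         method = c("additive")) {
  stopifnot(inherits(s, "spectrum_set"))
  method <- match.arg(method)
  wl <- s$wavelengths
  r <- s$reflectance
  for (j in sort(jump_wavelengths)) {
    if (!is.finite(j) || j < 355 || j > 2495)
      stop_validation("jump wavelength ", j, " outside the supported range [355, 2495] nm")
    i <- match(j, wl)
    if (is.na(i) || i < 6L || i + 6L > length(wl))
      stop_validation("jump wavelength ", j,
                      " is not inside the spectrum's grid (with a 5-point margin)")
    # first differences: d[t] = r[t+1, ] - r[t, ]; the splice difference is d[i]
    splice_diff <- r[i + 1L, ] - r[i, ]
    neigh <- rbind(
      r[(i - 4L):i, , drop = FALSE] - r[(i - 5L):(i - 1L), , drop = FALSE],
      r[(i + 2L):(i + 6L), , drop = FALSE] - r[(i + 1L):(i + 5L), , drop = FALSE]
    )
    target <- colMeans(neigh)
    offset <- splice_diff - target
    right <- (i + 1L):nrow(r)
    r[right, ] <- sweep(r[right, , drop = FALSE], 2L, offset, `-`)
  }
  s$reflectance <- r
  s
}

#' Write a trait predictions CSV
#'
#' One row per observation, observation names in the first column, then the
#' ten trait columns in the canonical [trait_names()] order. Round-trips
#' losslessly through [read_predictions_csv()].
#'
#' @param predictions Numeric matrix or data frame, rows named by observation,
#'   columns named by trait (any order; reordered canonically on write).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_predictions_csv <- function(predictions, path) {
  m <- as.matrix(predictions)
  if (nrow(m) > 0L && is.null(rownames(m)))
    stop_validation("predictions must carry observation names as row names")
  missing_traits <- setdiff(trait_names(), colnames(m))
  if (length(missing_traits))
    stop_validation("predictions lack trait column(s): ",
                    paste(missing_traits, collapse = ", "))
  m <- m[, trait_names(), drop = FALSE]
  df <- data.frame(observation = rownames(m), check.names = FALSE)
  if (nrow(m) == 0L) df <- data.frame(observation = character(0))
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("could not write predictions to ", path)
  invisible(path)
}

#' Read a trait predictions CSV
#'
#' @param path Path written by [write_predictions_csv()].
#' @return Numeric matrix, rows named by observation, columns the canonical
#'   traits.
#' @export
read_predictions_csv <- function(path) {
  if (!file.exists(path)) stop_schema("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "observation")
    stop_schema("first column must be 'observation'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  missing_traits <- setdiff(trait_names(), colnames(m))
  if (length(missing_traits))
    stop_schema("predictions CSV lacks trait column(s): ",
                paste(missing_traits, collapse = ", "))
  m[, trait_names(), drop = FALSE]
}
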