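#' Trim a spectrum set to a wavelength range
#'
#' Restricts the grid to the half-open interval `[low, high)`. The half-open
#' convention makes the default 400–2400 nm window exactly 2000 points
#' (400..2399), the fixed input length of the convolutional models; a closed
#' interval would give 2001. Spectra covering less than the requested window
#' are returned on their available sub-grid and zero-padded downstream by the
#' models.
#'
#' @param s A [spectrum_set()].
#' @param low,high Window bounds in nm; values at `low <= wl < high` are kept.
#' @return A [spectrum_set()] on the intersected grid.
#' @export
trim_to_range <- function(s, low = 400, high = 2400) {
  stopifnot(inherits(s, "spectrum_set"))
  assert_scalar_number(low, "low"); assert_scalar_number(high, "high")
  if (low >= high) stop_validation("low (", low, ") must be below high (", high, ")")
  keep <- s$wavelengths >= low & s$wavelengths < high
  if (!any(keep))
    stop_validation("window [", low, ", ", high, ") does not overlap the grid ",
                    min(s$wavelengths), "-", max(s$wavelengths), " nm")
  spectrum_set(s$wavelengths[keep], s$reflectance[keep, , drop = FALSE],
               provenance = s$provenance)
}

#' Remove spectra with implausible near-infrared reflectance
#'
#' Healthy leaf spectra show an NIR plateau; observations whose reflectance at
#' 800 nm falls outside \[0.35, 0.6\] are treated as measurement outliers
#' (bad clip contact, stray light) and removed. The band is inclusive: exact
#' boundary values are kept. Surviving spectra are returned bit-identical.
#'
#' @param s A [spectrum_set()] whose grid contains 800 nm.
#' @param band Inclusive acceptance band for R(800) (default `c(0.35, 0.6)`).
#' @return List with `kept` (a [spectrum_set()]) and `removed` (character
#'   vector of removed observation names).
#' @export
filter_outliers <- function(s, band = c(0.35, 0.6)) {
  stopifnot(inherits(s, "spectrum_set"))
  i <- match(800L, s$wavelengths)
  if (is.na(i)) stop_validation("grid does not contain 800 nm")
  r800 <- s$reflectance[i, ]
  bad <- r800 < band[1L] | r800 > band[2L]
  kept <- s
  kept$reflectance <- s$reflectance[, !bad, drop = FALSE]
  if (ncol(kept$reflectance) == 0L)
    stop_validation("all observations fall outside the R(800) band")
  list(kept = kept, removed = colnames(s$reflectance)[bad])
}

#' Average-pool a reflectance vector
#'
#' Non-overlapping arithmetic means over windows of `window` consecutive
#' values, the smoothing applied before every neural model to damp detector
#' noise. Vectors whose length is not a multiple of `window` are padded by
#' replicating the final value.
#'
#' @param v Numeric vector.
#' @param window Positive integer window (default 10).
#' @return Numeric vector of length `ceiling(length(v) / window)`.
#' @export
#' @examples
#' average_pool(1:20, 10)  # 5.5 15.5
average_pool <- function(v, window = 10L) {
  assert_scalar_number(window, "window")
  if (window < 1) stop_validation("window must be >= 1")
  window <- as.integer(window)
  n <- length(v)
  out_len <- ceiling(n / window)
  if (n %% window != 0L) v <- c(v, rep(v[n], out_len * window - n))
  colMeans(matrix(v, nrow = window))
}

#' Align spectra with trait labels
#'
#' Intersects observation names with trait sample ids, preserving spectra
#' order, and returns model-ready matrices.
#'
#' @param s A [spectrum_set()].
#' @param tm A [trait_matrix()].
#' @return List with `x` (samples x wavelengths matrix), `y` (samples x traits),
#'   `mask`, `ids`, `wavelengths`.
#' @export
align_spectra_traits <- function(s, tm) {
  stopifnot(inherits(s, "spectrum_set"), inherits(tm, "trait_matrix"))
  ids <- intersect(colnames(s$reflectance), tm$sample_ids)
  if (length(ids) == 0L) stop_validation("no sample ids shared between spectra and traits")
  j <- match(ids, tm$sample_ids)
  x <- t(s$reflectance[, ids, drop = FALSE])
  colnames(x) <- s$wavelengths
  list(x = x,
       y = tm$values[j, , drop = FALSE],
       mask = tm$mask[j, , drop = FALSE],
       ids = ids,
       wavelengths = s$wavelengths)
}

#' Partition samples into train / validation / test
#'
#' A single sample-level random split shared by all traits: each sample lands
#' wholly in one partition so the multi-task models never see a test sample's
#' spectrum during training, and per-trait effective counts then follow from
#' the missingness mask. Partition sizes are `floor(n * fraction)` for
#' validation and test with the remainder assigned to train.
#'
#' @param s A [spectrum_set()].
#' @param tm A [trait_matrix()] sharing sample ids with `s`.
#' @param fractions Length-3 numeric `(train, validation, test)` summing to 1
#'   (default `c(0.7, 0.1, 0.2)`).
#' @param seed Integer seed; the assignment is deterministic given `seed`.
#' @return An object of class `split_dataset`: the aligned data plus a
#'   `partition` factor (`train`/`validation`/`test`) and the seed.
#' @export
split_dataset <- function(s, tm, fractions = c(0.7, 0.1, 0.2), seed = 0L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop_validation("fractions must be three numbers summing to 1")
  al <- align_spectra_traits(s, tm)
  n <- length(al$ids)
  if (n < 3L) stop_validation("need at least 3 samples to split; got ", n)
  n_val <- floor(n * fractions[2L])
  n_test <- floor(n * fractions[3L])
  n_train <- n - n_val - n_test
  perm <- withr_seed_sample(seed, n)
  part <- factor(rep(NA_character_, n), levels = c("train", "validation", "test"))
  part[perm[seq_len(n_train)]] <- "train"
  part[perm[n_train + seq_len(n_val)]] <- "validation"
  part[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  structure(c(al, list(partition = part, seed = as.integer(seed),
                       fractions = fractions)),
            class = "split_dataset")
}

# Draw a permutation under a local RNG state so callers' streams are untouched.
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> n=", length(x$ids), " (",
      paste(table(x$partition), collapse = "/"), " train/val/test), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' Extract one partition of a split dataset
#'
#' @param d A [split_dataset()].
#' @param which One of `"train"`, `"validation"`, `"test"`.
#' @return List with `x`, `y`, `mask`, `ids`, `wavelengths` restricted to the
#'   partition.
#' @export
split_part <- function(d, which = c("train", "validation", "test")) {
  stopifnot(inherits(d, "split_dataset"))
  which <- match.arg(which)
  i <- d$partition == which
  list(x = d$x[i, , drop = FALSE], y = d$y[i, , drop = FALSE],
       mask = d$mask[i, , drop = FALSE], ids = d$ids[i],
       wavelengths = d$wavelengths)
}
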