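# Fixtures are built in code; nothing is read from disk.

# Pin BLAS/OpenMP to one thread before the first BLAS call: training results
# are documented as deterministic for a fixed thread count, and spinning
# threads oversubscribe single-CPU machines.
if (Sys.getenv("OPENBLAS_NUM_THREADS") == "")
  Sys.setenv(OPENBLAS_NUM_THREADS = "1")
if (Sys.getenv("OMP_NUM_THREADS") == "")
  Sys.setenv(OMP_NUM_THREADS = "1")

# Smooth leaf-like reflectance on an integer grid: visible trough, green
# peak, red edge to an NIR plateau, SWIR water dips.
leaf_curve <- function(wl, plateau = 0.48, red_edge = 720) {
  s <- 1 / (1 + exp(-(wl - red_edge) / 12))
  vis <- 0.06 + 0.035 * exp(-((wl - 550) / 35)^2)
  nir <- plateau - pmax(wl - 1300, 0) / 1100 * 0.08
  dip <- 0.16 * exp(-((wl - 1450) / 35)^2) + 0.28 * exp(-((wl - 1940) / 50)^2)
  (vis * (1 - s) + nir * s) * (1 - dip)
}

make_spectra <- function(n_obs = 3L, wl = 400:2399, plateau = 0.48) {
  r <- vapply(seq_len(n_obs),
              function(i) leaf_curve(wl, plateau = plateau + 0.01 * (i - 1)),
              numeric(length(wl)))
  colnames(r) <- paste0("obs", seq_len(n_obs))
  spectrum_set(wl, r, provenance = "fixture")
}

# Replace +/- `half` nm around each splice with a straight line so that an
# additive step is the only deviation from local linearity there — the regime
# in which splice correction recovers a planted step exactly.
linearise_at <- function(v, wl, splices, half = 7L) {
  for (j in splices) {
    i0 <- match(j - half, wl); i1 <- match(j + half, wl)
    v[i0:i1] <- seq(v[i0], v[i1], length.out = i1 - i0 + 1L)
  }
  v
}

splice_fixture <- function(n_obs = 2L, wl = 400:2399, splices = c(1000L, 1800L)) {
  r <- vapply(seq_len(n_obs),
              function(i) linearise_at(leaf_curve(wl, plateau = 0.46 + 0.02 * i),
                                       wl, splices),
              numeric(length(wl)))
  colnames(r) <- paste0("obs", seq_len(n_obs))
  spectrum_set(wl, r, provenance = "fixture")
}

# Direct-summation oracle for the dilated 1D convolution with "same" zero
# padding and stride 1: sums the printed per-position products with no shared
# code with the implementation.
conv_oracle <- function(x, w, b, dilation, relu = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  out_ch <- dim(w)[1L]; in_ch <- dim(w)[2L]; k <- dim(w)[3L]
  len <- ncol(x)
  half <- (k - 1L) %/% 2L
  out <- matrix(0, out_ch, len)
  for (co in seq_len(out_ch)) {
    for (pos in seq_len(len)) {
      acc <- b[co]
      for (ci in seq_len(in_ch)) {
        for (kk in seq_len(k)) {
          src <- pos + (kk - 1L - half) * dilation
          if (src >= 1L && src <= len) acc <- acc + w[co, ci, kk] * x[ci, src]
        }
      }
      out[co, pos] <- acc
    }
  }
  if (relu) out[out < 0] <- 0
  out
}

# Small aligned dataset for training smoke tests.
desk_dataset <- function(n = 200L, seed = 1L, label_noise = 0,
                         missingness = NULL) {
  cfg <- if (is.null(missingness))
    sim_config(n = n, seed = seed, label_noise = label_noise)
  else
    sim_config(n = n, seed = seed, label_noise = label_noise,
               missingness = missingness)
  d <- generate_dataset(cfg)
  s <- trim_to_range(jump_correct(d$spectra))
  split_dataset(filter_outliers(s)$kept, d$traits, seed = seed)
}

no_missing <- function() stats::setNames(rep(0, 10), trait_names())

# Constant-prediction stub for ensemble arithmetic.
stub_model <- function(value, traits = trait_names()) {
  structure(list(value = value, traits = traits), class = "stub_model")
}
.S3method("predict", "stub_model", function(object, newdata, ...) {
  n <- if (inherits(newdata, "spectrum_set")) ncol(newdata$reflectance)
       else nrow(newdata)
  matrix(object$value, n, length(object$traits),
         dimnames = list(NULL, object$traits))
})
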