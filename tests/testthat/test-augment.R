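test_that("horizontal shifts translate with edge replication", {
  expect_identical(random_shift(1:10, 0), 1:10)
  expect_identical(random_shift(1:10, 2), c(1L, 1L, 1:8))
  expect_identical(random_shift(1:10, -2), c(3:10, 10L, 10L))
  expect_error(random_shift(1:10, 6), "<= 5")
  expect_error(random_shift(1:10, 1.5), "integer")
})

test_that("shift expansion appends round(n * rate) copies, originals first", {
  set.seed(1)
  train <- list(x = matrix(rnorm(772 * 12), 772,
                           dimnames = list(NULL, 400:411)),
                y = matrix(rnorm(772 * 10), 772,
                           dimnames = list(NULL, trait_names())),
                mask = matrix(TRUE, 772, 10,
                              dimnames = list(NULL, trait_names())),
                ids = paste0("s", 1:772))
  out <- expand_training_set(train, 0.5, seed = 2)
  expect_equal(nrow(out$x), 1158L)
  expect_identical(out$x[1:772, ], train$x)
  expect_identical(out$y[1:772, ], train$y)
  # deterministic given the seed
  out2 <- expand_training_set(train, 0.5, seed = 2)
  expect_identical(out, out2)

  small <- lapply(train, function(m) if (is.matrix(m)) m[1:10, ] else m[1:10])
  expect_equal(nrow(expand_training_set(small, 0.5, seed = 1)$x), 15L)
  expect_identical(expand_training_set(train, 0), train)
  empty <- lapply(train, function(m) if (is.matrix(m)) m[0, , drop = FALSE] else m[0])
  expect_error(expand_training_set(empty, 0.5), "empty")
})

test_that("every augmented copy is a shifted original with identical labels", {
  set.seed(3)
  train <- list(x = matrix(rnorm(20 * 30), 20, dimnames = list(NULL, 400:429)),
                y = matrix(rnorm(20 * 10), 20, dimnames = list(NULL, trait_names())),
                mask = matrix(TRUE, 20, 10, dimnames = list(NULL, trait_names())))
  out <- expand_training_set(train, 1, seed = 4)
  for (i in 21:40) {
    hits <- vapply(1:20, function(src) {
      any(vapply(c(-5:-1, 1:5), function(sh)
        isTRUE(all.equal(unname(out$x[i, ]),
                         unname(random_shift(train$x[src, ], sh)))),
        logical(1)))
    }, logical(1))
    expect_true(any(hits))
    src <- which(hits)[1]
    expect_equal(out$y[i, ], train$y[src, ])
  }
})

test_that("trim bound sampling respects bounds, span and the marginals", {
  dist <- trim_distribution()
  set.seed(10)
  b <- sample_trim_bounds(dist, 20000L)
  expect_true(all(b[, "low"] >= 400 & b[, "low"] <= 700))
  expect_true(all(b[, "high"] >= 1000 & b[, "high"] <= 2400))
  expect_true(all(b[, "high"] - b[, "low"] >= 350))

  # independent rejection-sampling oracle: raw normals, reject out-of-bounds
  # draws and short spans
  set.seed(11)
  lo <- numeric(0); hi <- numeric(0)
  while (length(lo) < 20000L) {
    l <- rnorm(60000, 400, 100); h <- rnorm(60000, 2400, 500)
    ok <- l >= 400 & l <= 700 & h >= 1000 & h <= 2400 & (h - l) >= 350
    lo <- c(lo, l[ok]); hi <- c(hi, h[ok])
  }
  for (pair in list(list(b[, "low"], lo), list(b[, "high"], hi))) {
    se <- sqrt(var(pair[[1]]) / length(pair[[1]]) + var(pair[[2]]) / length(pair[[2]]))
    expect_lt(abs(mean(pair[[1]]) - mean(pair[[2]])), 3 * se)
  }
})

test_that("an unconstrained sampler matches the closed-form truncated mean", {
  # min_span 300 is never binding (low <= 700, high >= 1000), so the low
  # marginal is the plain truncated normal with a closed-form mean
  dist <- trim_distribution(min_span = 300)
  set.seed(12)
  b <- sample_trim_bounds(dist, 50000L)
  a <- (400 - 400) / 100; bb <- (700 - 400) / 100
  m_closed <- 400 + 100 * (dnorm(a) - dnorm(bb)) / (pnorm(bb) - pnorm(a))
  se <- sd(b[, "low"]) / sqrt(nrow(b))
  expect_lt(abs(mean(b[, "low"]) - m_closed), 3 * se)
})

test_that("a degenerate zero-sd distribution collapses to the full window", {
  dist <- trim_distribution(low_sd = 0, high_sd = 0)
  b <- sample_trim_bounds(dist, 5L)
  expect_true(all(b[, "low"] == 400 & b[, "high"] == 2400))
})

test_that("spectral trimming zeroes outside the window and is idempotent", {
  wl <- 400:2399
  v <- leaf_curve(wl)
  expect_identical(apply_spectral_trim(v, wl, 400, 2399), v)
  out <- apply_spectral_trim(v, wl, 500, 1700)
  expect_true(all(out[wl < 500] == 0))
  expect_true(all(out[wl > 1700] == 0))
  expect_identical(out[wl >= 500 & wl <= 1700], v[wl >= 500 & wl <= 1700])
  expect_length(out, length(v))
  expect_identical(apply_spectral_trim(out, wl, 500, 1700), out)
  expect_error(apply_spectral_trim(v, wl, 1700, 500), "below")
})
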