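test_that("generation is deterministic given the configuration", {
  a <- generate_dataset(sim_config(n = 50, seed = 4))
  b <- generate_dataset(sim_config(n = 50, seed = 4))
  expect_identical(a$spectra$reflectance, b$spectra$reflectance)
  expect_identical(a$traits$values, b$traits$values)
  c2 <- generate_dataset(sim_config(n = 50, seed = 5))
  expect_false(identical(a$spectra$reflectance, c2$spectra$reflectance))
})

test_that("non-outlier spectra satisfy the R(800) quality band", {
  d <- generate_dataset(sim_config(n = 400, seed = 2))
  i800 <- match(800L, d$spectra$wavelengths)
  r800 <- d$spectra$reflectance[i800, ]
  ok <- !(colnames(d$spectra$reflectance) %in% d$truth$outliers)
  expect_true(all(r800[ok] >= 0.35 & r800[ok] <= 0.6))
  # planted outliers are exactly round(n * fraction) and all fall outside
  expect_length(d$truth$outliers, round(400 * 0.02))
  expect_true(all(r800[!ok] < 0.35 | r800[!ok] > 0.6))
  expect_true(all(d$spectra$reflectance >= 0 & d$spectra$reflectance <= 1))
})

test_that("trait marginals reproduce the reference moments at n = 2000", {
  d <- generate_dataset(sim_config(n = 2000, seed = 3))
  ref <- spectratraits:::trait_reference_moments()
  vals <- d$truth$values
  for (i in seq_len(nrow(ref))) {
    v <- vals[, ref$trait[i]]
    se_mean <- ref$sd[i] / sqrt(2000)
    se_sd <- ref$sd[i] / sqrt(2 * (2000 - 1))
    expect_lt(abs(mean(v) - ref$mean[i]), 3 * se_mean)
    expect_lt(abs(sd(v) - ref$sd[i]), 3 * se_sd)
  }
  # missingness follows the per-trait reference counts
  obs <- colSums(d$traits$mask)
  expect_true(all(abs(obs / 2000 - ref$n / 1013) < 0.05))
})

test_that("planted trait-feature linkages are recovered by regression", {
  d <- generate_dataset(sim_config(n = 600, seed = 8))
  pl <- d$truth$planted
  for (i in seq_len(nrow(pl))) {
    trait <- pl$trait[i]
    # stay inside both the rendering clamp (|z| < 2.5) and the positive
    # floor applied to small-valued traits
    keep <- abs(d$truth$z[, trait]) < 2.2 &
      !(d$traits$sample_ids %in% d$truth$outliers)
    fit <- lm(d$truth$values[keep, trait] ~ d$truth$features[keep, pl$feature[i]])
    expect_equal(unname(coef(fit)[2]), pl$slope[i], tolerance = 1e-6)
    expect_equal(unname(coef(fit)[1]), pl$intercept[i], tolerance = 1e-6)
  }
})

test_that("trait correlations follow the configured matrix", {
  d <- generate_dataset(sim_config(n = 2000, seed = 9))
  emp <- cor(d$truth$z)
  expect_lt(max(abs(emp - default_trait_correlation())), 0.1)
})

test_that("detector jump injection is additive, cumulative and validated", {
  s <- make_spectra(2L)
  expect_identical(inject_detector_jumps(s, c("1000" = 0))$reflectance,
                   s$reflectance)
  j <- inject_detector_jumps(s, c("1000" = 0.05, "1800" = 0.02))
  wl <- s$wavelengths
  expect_equal(j$reflectance[wl <= 1000, ], s$reflectance[wl <= 1000, ])
  expect_equal(j$reflectance[wl > 1000 & wl <= 1800, ],
               s$reflectance[wl > 1000 & wl <= 1800, ] + 0.05)
  expect_equal(j$reflectance[wl > 1800, ], s$reflectance[wl > 1800, ] + 0.07)
  # the 1830 nm splice position used by some instruments is accepted
  expect_silent(inject_detector_jumps(s, c("1830" = 0.05)))
  expect_error(inject_detector_jumps(s, c("3000" = 0.05)), "grid")
  expect_error(inject_detector_jumps(s, 0.05), "named")
})

test_that("generator jumps are substantially removed by jump correction", {
  d <- generate_dataset(sim_config(n = 30, seed = 10))
  corrected <- jump_correct(d$spectra, c(1000L, 1800L))
  dev_before <- max(abs(d$spectra$reflectance - d$truth$clean$reflectance))
  dev_after <- max(abs(corrected$reflectance - d$truth$clean$reflectance))
  expect_gt(dev_before, 0.015)   # the planted steps are visible
  expect_lt(dev_after, 0.02)     # residual limited by local noise, not steps
  expect_lt(dev_after, dev_before / 2)
})

test_that("infeasible correlation matrices are rejected", {
  bad <- default_trait_correlation()
  bad[1, 2] <- bad[2, 1] <- 2
  expect_error(sim_config(correlation = bad), "positive semi-definite")
  asym <- default_trait_correlation(); asym[1, 2] <- asym[1, 2] + 0.2
  expect_error(sim_config(correlation = asym), "symmetric")
})
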