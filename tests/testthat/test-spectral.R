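test_that("preprocessing epochs, rejects artifacts and low-passes", {
  rec <- fix_recording(duration = 60)
  es <- preprocess(rec)
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$epochs)[1], 12L)    # 60 s / 5 s
  expect_equal(es$rejected, 0L)
  # inject a 500 uV step into epoch 3 -> that epoch is rejected
  rec2 <- rec
  rec2$samples[4, 3000:3100] <- rec2$samples[4, 3000:3100] + 500
  es2 <- preprocess(rec2)
  expect_equal(dim(es2$epochs)[1], 11L)
  expect_equal(es2$rejected, 1L)
  # post-filter power above 45 Hz is a sliver of the total
  x <- es$epochs[1, 1, ]
  W <- welch_csd(matrix(x, 1), rec$rate, nseg = 250)
  hi <- sum(Re(W$S[1, 1, W$freqs > 45]))
  expect_lt(hi / sum(Re(W$S[1, 1, ])), 0.01)
  # all epochs rejected is an explicit error
  rec3 <- rec
  rec3$samples <- rec3$samples * 100
  expect_error(preprocess(rec3), "no epochs")
  expect_error(preprocess(recording(matrix(0, 21, 10), 250)), "shorter")
})

test_that("spatial modes are orthonormal and capture low-rank structure", {
  # three independent sources mixed into 21 channels
  set.seed(8)
  n <- 3 * 250 * 5
  src <- matrix(rnorm(3 * n, 0, 20), 3)
  mix <- matrix(rnorm(21 * 3), 21)
  rec <- recording(mix %*% src + matrix(rnorm(21 * n, 0, 0.1), 21), 250)
  es <- preprocess(rec, amplitude_threshold = Inf,
                   gradient_threshold = Inf)
  sm <- compute_spatial_modes(es, k = 8)
  expect_lt(max(abs(crossprod(sm$M) - diag(8))), 1e-10)
  # singular values 4..8 sit at the noise floor
  expect_lt(sm$singular_values[4] / sm$singular_values[3], 0.05)
  # completeness: with k = n_channels the projection preserves variance
  sm_full <- compute_spatial_modes(es, k = 21)
  X <- matrix(aperm(es$epochs, c(2, 3, 1)), nrow = 21)
  X <- X - rowMeans(X)
  expect_equal(sum((t(sm_full$M) %*% X)^2), sum(X^2), tolerance = 1e-9)
  expect_error(compute_spatial_modes(es, k = 22), "channel")
})

test_that("autoregressive cross-spectra match the AR(1) closed form", {
  set.seed(10)
  a <- 0.5; sig <- 2; fs <- 250
  n <- 3e5
  x <- as.numeric(stats::filter(rnorm(n, 0, sig), a, "recursive"))
  es <- list(epochs = array(x, c(1, 1, n)), rate = fs, channels = "ch1")
  class(es) <- "epoch_set"
  cs <- mar_cross_spectra(es, matrix(1, 1, 1), order = 1,
                          band = c(2, 48), df = 1)
  f <- cs$freqs
  closed <- sig^2 / fs / Mod(1 - a * exp(-2i * pi * f / fs))^2
  rel <- sqrt(sum((Re(cs$S[1, 1, ]) - closed)^2) / sum(closed^2))
  expect_lt(rel, 0.01)
})

test_that("independent white-noise modes have vanishing cross-spectra", {
  set.seed(12)
  nep <- 40
  es <- list(epochs = array(rnorm(nep * 3 * 500), c(nep, 3, 500)),
             rate = 250, channels = paste0("m", 1:3))
  class(es) <- "epoch_set"
  cs <- mar_cross_spectra(es, diag(3), order = 2, band = c(5, 40), df = 5)
  off <- max(Mod(cs$S[1, 2, ]), Mod(cs$S[1, 3, ]), Mod(cs$S[2, 3, ]))
  diag_ <- min(Re(cs$S[1, 1, ]))
  expect_lt(off / diag_, 0.15)
  for (i in seq_along(cs$freqs)) {
    sl <- cs$S[, , i]
    expect_equal(max(Mod(sl - t(Conj(sl)))), 0, tolerance = 1e-12)
    expect_true(all(Re(diag(sl)) >= 0))
  }
})

test_that("estimated spectra converge to the analytic MAR spectrum", {
  # seeded bivariate AR(1) with known coefficient matrix
  set.seed(14)
  A1 <- matrix(c(0.5, 0.2, -0.1, 0.3), 2)
  Sig <- diag(c(1, 0.5))
  fs <- 250
  n <- 4e5
  x <- matrix(0, 2, n)
  innov <- rbind(rnorm(n), rnorm(n, 0, sqrt(0.5)))
  for (t in 2:n) x[, t] <- A1 %*% x[, t - 1] + innov[, t]
  es <- list(epochs = array(x, c(1, 2, n)), rate = fs,
             channels = c("m1", "m2"))
  class(es) <- "epoch_set"
  cs <- mar_cross_spectra(es, diag(2), order = 1, band = c(2, 48), df = 2)
  num <- den <- 0
  for (i in seq_along(cs$freqs)) {
    Af <- diag(2) - A1 * exp(-2i * pi * cs$freqs[i] / fs)
    H <- solve(Af)
    St <- H %*% Sig %*% t(Conj(H)) / fs
    num <- num + sum(Mod(cs$S[, , i] - St)^2)
    den <- den + sum(Mod(St)^2)
  }
  expect_lt(sqrt(num / den), 0.10)
})

test_that("band data-point counts match the fitted feature tallies", {
  expect_equal(count_data_points(c(20, 48), 1, 8), 1856L)
  expect_equal(count_data_points(c(2, 6), 1, 8), 320L)
  expect_equal(count_data_points(c(10, 10), 1, 1), 1L)
  expect_error(count_data_points(c(6, 2)), "empty")
  expect_error(count_data_points(c(2, 6), df = 0.7), "divide")
})

test_that("band power summaries average the chosen autospectrum", {
  f <- 1:48
  S <- array(0i, c(2, 2, 48))
  S[1, 1, ] <- 3          # flat spectrum
  S[2, 2, ] <- exp(-(f - 30)^2 / 18)   # Gaussian bump, mode 2
  cs <- cross_spectra(f, S)
  expect_equal(band_power_summary(cs, c(10, 20), 1), 3)
  expect_equal(band_power_summary(cs, c(7, 7), 1), 3)
  # quadrature oracle for the bump
  expect_equal(band_power_summary(cs, c(25, 35), 2),
               mean(exp(-((25:35) - 30)^2 / 18)), tolerance = 1e-12)
  expect_error(band_power_summary(cs, c(10, 20), 5), "out of range")
})

test_that("group band-power ANOVA agrees with a sum-of-squares oracle", {
  y <- c(1.2, 1.5, 1.1, 2.2, 2.0, 2.4, 1.3, 1.4, 1.2)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- group_band_anova(y, g)
  # from-scratch decomposition
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, Fo, tolerance = 1e-10)
  expect_equal(res$df, c(2, 6))
  # identical groups give F = 0
  expect_equal(group_band_anova(rep(5, 9), g)$F, 0)
  # only comparisons involving the shifted group are significant
  set.seed(3)
  y2 <- c(rnorm(8), rnorm(8), rnorm(8) + 6)
  g2 <- rep(c("a", "b", "c"), each = 8)
  pw <- group_band_anova(y2, g2)$pairwise
  hit <- pw$p_corrected < 0.05
  involves_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(hit[involves_c]))
  expect_false(any(hit[!involves_c]))
  expect_error(group_band_anova(y[1:3], g[1:3]), "two groups")
})

test_that("EDF recordings survive a write/read round trip", {
  rec <- fix_recording(duration = 6, amp = 15)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  rec2 <- read_edf(path)
  expect_equal(rec2$rate, rec$rate)
  expect_equal(rec2$channels, rec$channels)
  # 16-bit quantization: amplitudes agree to the quantization step
  rng <- max(rec$samples) - min(rec$samples)
  expect_lt(max(abs(rec2$samples - rec$samples)), rng / 65536 * 2)
})
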