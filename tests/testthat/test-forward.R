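test_that("the fixed point solves the state equations", {
  net <- fix_net()
  x <- find_fixed_point(NULL, net)
  expect_lte(attr(x, "residual"), 1e-8)
  eq <- assemble_state_equations(net)
  expect_lt(max(abs(eq$f(as.numeric(x)))), 1e-7)
  # conductance fixed points equal the coupling-weighted presynaptic rates
  ctx <- resolve_params(NULL, net)$ctx
  rates <- sapply(1:4, function(p)
    presynaptic_rate(x[(p - 1) * 4 + 1], threshold = ctx$VR,
                     variance = ctx$sigma^2))
  # GABA-A receives no extrinsic input, so its fixed point is purely the
  # intrinsic coupling-weighted rates
  gG_sp <- x[7]      # source 1, SP population, GABA-A conductance
  expect_equal(gG_sp, sum(ctx$WG[2, , 1] * rates), tolerance = 1e-6)
  # hemispheric symmetry: homologous sources share the same fixed point
  expect_equal(as.numeric(x)[1:16], as.numeric(x)[17:32],
               tolerance = 1e-6)
})

test_that("transfer functions reduce to the Lorentzian for one state", {
  a <- 0.11    # ms^-1
  lin <- list(Jd = matrix(-a, 1, 1), max_real = -a)
  f <- c(1, 5, 20, 40)
  H <- transfer_functions(lin, f, Out = matrix(1), B = matrix(1))
  expect_equal(as.numeric(Mod(H[1, 1, ])^2),
               1 / (a^2 + (2 * pi * f / 1000)^2), tolerance = 1e-12)
})

test_that("the DC transfer gain equals -Out J^-1 B", {
  net <- fix_net()
  lin <- linearize(NULL, net)
  set.seed(1)
  Out <- matrix(rnorm(2 * 64), 2)
  B <- matrix(0, 64, 1); B[1, 1] <- 1
  H0 <- transfer_functions(lin, 0, Out, B)
  expect_equal(H0[, , 1], as.numeric(-Out %*% solve(lin$Jd, B)) + 0i,
               tolerance = 1e-8)
})

test_that("predicted cross-spectra are Hermitian PSD for valid parameters", {
  fwd <- fix_fwd(freqs = c(3, 10, 25, 40))
  set.seed(21)
  for (r in 1:5) {
    lam <- setNames(rnorm(41, 0, 0.1), param_labels(fwd$net))
    cs <- predicted_csd(lam, fwd)
    for (i in seq_along(cs$freqs)) {
      sl <- cs$S[, , i]
      expect_lt(max(Mod(sl - t(Conj(sl)))), 1e-10 * max(Mod(sl)))
      ev <- eigen(sl, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(Re(ev)), -1e-10 * max(Re(ev)))
    }
  }
})

test_that("noise-free predictions have rank at most the source count", {
  fwd <- fix_fwd(freqs = c(5, 25))
  cs <- predicted_csd(c(noise.c_amp = -30), fwd)
  for (i in 1:2) {
    d <- svd(cs$S[, , i])$d
    expect_lt(d[5] / d[1], 1e-10)
  }
})

test_that("power scales with the square of the innovations amplitude", {
  fwd <- fix_fwd(freqs = c(5, 25))
  s1 <- predicted_csd(c(noise.c_amp = -30), fwd)
  s2 <- predicted_csd(c(noise.u_amp = log(2), noise.c_amp = -30), fwd)
  expect_equal(s2$S, 4 * s1$S, tolerance = 1e-9)
})

test_that("prediction and cohort generator share one forward model", {
  # the analytic prediction reproduces the generator's noiseless channel
  # spectra exactly (same compiled code path)
  net <- fix_net()
  lf <- fix_lf(net)
  M <- fix_modes(lf)
  spec <- cohort_spec(sensor_noise_sd = 0, channel_gain = 1)
  S_ch <- cmcEEG:::channel_csd(NULL, net, lf, 2:6, spec, cmc_constants())
  Sm <- array(0i, c(8, 8, 5))
  for (k in 1:5) Sm[, , k] <- t(M) %*% S_ch[, , k] %*% M
  fwd <- forward_model(net, lf, M, 2:6)
  P <- predicted_csd(c(noise.c_amp = -30), fwd)
  expect_equal(Sm, P$S, tolerance = 1e-10)
})

test_that("compiled spectra match the reference transfer-function route", {
  # dual route: the R-side compensated-Jacobian transfer functions against
  # the compiled path evaluated under the same delay convention
  net <- fix_net()
  lin <- linearize(NULL, net)
  fwd <- fix_fwd(freqs = c(3, 25), exact_delays = FALSE)
  Hr <- transfer_functions(lin, c(3, 25), fwd$Out, fwd$B)
  P <- predicted_csd(c(noise.c_amp = -30), fwd)
  for (k in 1:2) {
    S1 <- Hr[, , k] %*% t(Conj(Hr[, , k]))   # unit white innovations
    expect_lt(max(Mod(P$S[, , k] - S1)) / max(Mod(P$S[, , k])), 1e-8)
  }
})

test_that("instability raises a typed error carrying the margin", {
  lin <- list(Jd = matrix(0.02, 1, 1), max_real = 0.02)
  err <- tryCatch(transfer_functions(lin, 10, matrix(1), matrix(1)),
                  cmcEEG_unstable = identity)
  expect_s3_class(err, "cmcEEG_unstable")
  expect_equal(err$max_real, 0.02)
})

test_that("variance explained is 100 for identical and affine spectra", {
  fwd <- fix_fwd(freqs = 2:6)
  cs <- predicted_csd(NULL, fwd)
  expect_equal(fit_variance_explained(cs, cs), 100)
  cs2 <- cs
  cs2$S <- 3 * cs$S
  expect_equal(fit_variance_explained(cs, cs2), 100, tolerance = 1e-9)
  # arithmetic oracle on a 4-element toy
  a <- c(1, 2, 3, 5); b <- c(1.1, 1.9, 3.4, 4.6)
  Sa <- array(0i, c(2, 2, 1)); Sb <- Sa
  Sa[, , 1] <- matrix(a, 2); Sa[, , 1] <- (Sa[, , 1] + t(Sa[, , 1])) / 2
  Sb[, , 1] <- matrix(b, 2); Sb[, , 1] <- (Sb[, , 1] + t(Sb[, , 1])) / 2
  ca <- cross_spectra(1, Sa); cb <- cross_spectra(1, Sb)
  va <- as.numeric(Mod(Sa[, , 1])); vb <- as.numeric(Mod(Sb[, , 1]))
  oracle <- 100 * (sum((va - mean(va)) * (vb - mean(vb))) /
                     sqrt(sum((va - mean(va))^2) *
                            sum((vb - mean(vb))^2)))^2
  expect_equal(fit_variance_explained(ca, cb), oracle, tolerance = 1e-10)
  # constant vectors are rejected
  Sc <- array(2 + 0i, c(2, 2, 1))
  expect_error(fit_variance_explained(cross_spectra(1, Sc), cb),
               "undefined")
})

test_that("cross-spectra survive the array-container round trip", {
  fwd <- fix_fwd(freqs = 2:4)
  cs <- predicted_csd(NULL, fwd)
  path <- withr::local_tempfile(fileext = ".json")
  write_csd(cs, path, modes = fwd$modes)
  back <- read_csd(path)
  expect_equal(back$csd$S, cs$S, tolerance = 1e-12)
  expect_equal(back$csd$freqs, cs$freqs)
  expect_equal(back$modes, fwd$modes, tolerance = 1e-12,
               ignore_attr = TRUE)
})
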