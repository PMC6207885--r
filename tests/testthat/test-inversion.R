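test_that("free-energy components behave as accuracy minus complexity", {
  pr <- list(mean = c(0, 0), cov = diag(2))
  J <- matrix(0, 3, 2)
  # posterior = prior with zero residuals: complexity vanishes
  ft <- cmcEEG:::fe_terms(e = rep(0, 3), J = J, Sigma = diag(2),
                          mu = c(0, 0), priors = pr, tau = 1)
  expect_equal(ft$complexity, 0, tolerance = 1e-12)
  # widening the prior shrinks the penalty for a displaced posterior
  # (posterior covariance matched to the prior so only the mean deviation
  # is penalized)
  ft2 <- cmcEEG:::fe_terms(e = rep(0, 3), J = J, Sigma = diag(2),
                           mu = c(0.5, -0.2),
                           priors = list(mean = c(0, 0), cov = diag(2)),
                           tau = 1)
  ft3 <- cmcEEG:::fe_terms(e = rep(0, 3), J = J, Sigma = diag(4, 2),
                           mu = c(0.5, -0.2),
                           priors = list(mean = c(0, 0),
                                         cov = diag(4, 2)),
                           tau = 1)
  expect_lt(ft3$complexity, ft2$complexity)
})

test_that("the conjugate linear-Gaussian toy is solved exactly", {
  toy <- toy_linear()
  model <- function(theta) as.numeric(toy$A %*% theta)
  post <- variational_laplace(toy$y, model, toy$priors,
                              vl_control(max_iter = 64, tau = toy$tau,
                                         tol = 1e-10, min_iter = 5))
  # free energy at convergence equals the analytic log evidence
  expect_equal(post$F, toy$logZ, tolerance = 1e-6)
  # posterior matches the conjugate closed form
  expect_equal(unname(post$mean), toy$post_mean, tolerance = 1e-6)
  expect_equal(post$cov, toy$post_cov, tolerance = 1e-6)
})

test_that("accepted free energies are monotone and R2 is near-perfect", {
  post <- experiment_roundtrip(n_epochs = Inf, max_iter = 12)
  expect_true(all(diff(post$trace) >= -1e-9))
  expect_gte(post$R2, 99)
})

test_that("parameters are recovered from data generated near the prior", {
  fwd <- fix_fwd(freqs = 2:6)
  S <- predicted_csd(NULL, fwd)
  set.seed(31)
  Sn <- cmcEEG:::sample_csd(S$S, 5000)   # tiny sampling noise
  obs <- cross_spectra(2:6, Sn, tol = 1e-6)
  post <- variational_laplace(obs, fwd, default_priors(fwd$net),
                              vl_control(max_iter = 16))
  sd_ <- sqrt(diag(post$cov))
  within <- abs(as.numeric(post$mean)) <= 2 * sd_
  expect_gte(mean(within), 0.9)
})

test_that("empirical prior calibration averages reference posteriors", {
  pr <- default_priors(fix_net())
  mk <- function(v) {
    p <- list(mean = setNames(rep(v, length(pr$mean)), pr$labels),
              cov = diag(length(pr$mean)))
    class(p) <- "cmc_posterior"
    p
  }
  one <- calibrate_empirical_priors(list(mk(0.3)), pr)
  expect_equal(unname(one$mean), rep(0.3, length(pr$mean)))
  three <- calibrate_empirical_priors(list(mk(0.1), mk(0.2), mk(0.6)), pr)
  expect_equal(unname(three$mean), rep(0.3, length(pr$mean)),
               tolerance = 1e-12)
  expect_equal(three$cov, pr$cov)
  expect_error(calibrate_empirical_priors(list(), pr), "no posteriors")
})

test_that("the cohort pipeline calibrates on three random controls", {
  spec <- cohort_spec(n_control = 4, n_encephalopathy = 1, n_nmdar = 1,
                      master_seed = 5)
  co <- generate_cohort(spec)
  post <- invert_cohort(co, band = "delta",
                        control = vl_control(max_iter = 3, min_iter = 1),
                        empirical_calibration = TRUE,
                        calibration_seed = 2)
  pr <- attr(post, "priors")
  # the calibrated prior mean is no longer the zero vector, and every
  # subject's inversion used it
  expect_gt(max(abs(pr$mean)), 0)
  expect_equal(post[[1]]$priors$mean, pr$mean)
})

test_that("model comparison sums per-subject evidence differences", {
  Fd <- c(s1 = -100, s2 = -90, s3 = -80)
  Fv <- c(s1 = -98, s2 = -94, s3 = -75)
  cm <- compare_models(Fd, Fv)
  expect_equal(unname(cm$dF), c(2, -4, 5))
  expect_equal(cm$total, sum(cm$dF))
  expect_equal(cm$winner, "variant")
  expect_equal(compare_models(Fd, Fd)$total, 0)
  expect_error(compare_models(Fd, Fv[1:2]), "differ")
})

test_that("the model variant is recovered from variant-generated spectra", {
  # data generated WITH the SP->SS NMDA interconnection (strong link so
  # the comparison is informative); the variant must win on summed dF
  netV <- build_default_network(include_sp_to_ss = TRUE)
  net0 <- build_default_network()
  KV <- cmc_constants(w_spss_nmda = 1.2)
  lf <- fix_lf(net0)
  M <- fix_modes(lf)
  spec <- cohort_spec(subject_sd = 0.05)
  dF <- numeric(3)
  for (s in 1:3) {
    set.seed(300 + s)
    lam <- setNames(rnorm(41, 0, 0.05), param_labels(netV))
    S <- cmcEEG:::channel_csd(c(lam, setNames(numeric(3), noise_labels())),
                              netV, lf, 2:6, spec, KV)
    Sm <- array(0i, c(8, 8, 5))
    for (k in 1:5) Sm[, , k] <- t(M) %*% S[, , k] %*% M
    set.seed(400 + s)
    Sm <- cmcEEG:::sample_csd(Sm, 144)
    obs <- cross_spectra(2:6, Sm, tol = 1e-6)
    pV <- variational_laplace(obs,
                              forward_model(netV, lf, M, 2:6,
                                            constants = KV),
                              default_priors(netV),
                              vl_control(max_iter = 12))
    p0 <- variational_laplace(obs,
                              forward_model(net0, lf, M, 2:6,
                                            constants = KV),
                              default_priors(net0),
                              vl_control(max_iter = 12))
    dF[s] <- pV$F - p0$F
  }
  cm <- compare_models(setNames(numeric(3), paste0("s", 1:3)),
                       setNames(dF, paste0("s", 1:3)))
  expect_equal(cm$winner, "variant")
  expect_gt(cm$total, 0)
})
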