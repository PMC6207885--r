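test_that("the design matrix codes nested group membership", {
  X <- build_design(c("control", "encephalopathy", "nmdar"))
  expect_equal(unname(X),
               rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  expect_equal(colnames(X), c("mean", "encephalopathy", "nmdar"))
  X0 <- build_design(rep("control", 5))
  expect_equal(sum(X0[, 2:3]), 0)
  # cohort-sized column sums
  Xc <- build_design(rep(c("nmdar", "encephalopathy", "control"),
                         c(29, 18, 18)))
  expect_equal(unname(colSums(Xc)), c(65, 47, 29))
  expect_error(build_design(c("control", "patient")), "unknown")
})

test_that("canonical variates analysis finds perfect and partial couplings", {
  set.seed(51)
  n <- 40
  g <- rep(0:1, each = n / 2)
  # a parameter column that copies the indicator gives correlation 1
  Y <- cbind(g, matrix(rnorm(n * 3), n))
  r <- cva(Y, g)
  expect_equal(r$cor[1], 1, tolerance = 1e-8)
  # grid-search oracle on a 2-parameter toy
  set.seed(52)
  Y2 <- cbind(g + rnorm(n, 0, 0.8), rnorm(n))
  r2 <- cva(Y2, g)
  ang <- seq(0, pi, length.out = 2000)
  Y2c <- scale(Y2, scale = FALSE)
  Xc <- g - mean(g)
  grid_best <- max(vapply(ang, function(a) {
    w <- c(cos(a), sin(a))
    abs(stats::cor(Y2c %*% w, Xc))
  }, 0))
  expect_equal(r2$cor[1], grid_best, tolerance = 1e-3)
  # cross-check against the reference implementation in stats
  cc <- stats::cancor(Y2c, matrix(Xc))
  expect_equal(r2$cor[1], cc$cor[1], tolerance = 1e-8)
})

test_that("Bartlett p-values are calibrated and reparameterization-invariant", {
  set.seed(53)
  n <- 60
  rej <- mean(replicate(500, {
    Y <- matrix(rnorm(n * 3), n)
    X <- rnorm(n)
    cva(Y, X)$p < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)
  # invertible linear reparameterization of X leaves the test unchanged
  Y <- matrix(rnorm(n * 4), n)
  X <- cbind(rnorm(n), rnorm(n))
  T_ <- matrix(c(2, 1, -1, 1), 2)
  expect_equal(cva(Y, X)$p, cva(Y, X %*% T_)$p, tolerance = 1e-9)
  expect_error(cva(matrix(rnorm(8), 2), c(0, 1)), "rank")
})

test_that("PEB reduces to the average for identical subjects", {
  net <- fix_net()
  labs <- param_labels(net)
  m <- setNames(rnorm(length(labs), 0, 0.2), labs)
  post <- lapply(1:6, function(i)
    list(mean = m, cov = diag(0.05^2, length(labs))))
  X <- matrix(1, 6, 1, dimnames = list(NULL, "mean"))
  # with a vague effect prior the estimate is the (common) posterior mean
  peb <- peb_fit(post, X, parameters = labs, optimize_hyper = FALSE,
                 beta_prior_variance = 1e4)
  expect_equal(unname(peb$beta[, 1]), unname(m), tolerance = 1e-3)
})

test_that("PEB is invariant to joint subject permutation", {
  net <- fix_net()
  labs <- param_labels(net)
  set.seed(55)
  groups <- rep(c("control", "encephalopathy", "nmdar"), c(4, 4, 5))
  post <- lapply(seq_along(groups), function(i)
    list(mean = setNames(rnorm(length(labs), 0, 0.1), labs),
         cov = diag(0.04^2, length(labs))))
  X <- build_design(groups)
  p1 <- peb_fit(post, X, parameters = labs, optimize_hyper = FALSE)
  perm <- sample(length(groups))
  p2 <- peb_fit(post[perm], X[perm, ], parameters = labs,
                optimize_hyper = FALSE)
  expect_equal(p1$beta, p2$beta, tolerance = 1e-8)
})

test_that("a planted group effect is recovered within 2 posterior SDs", {
  net <- fix_net()
  labs <- param_labels(net)
  target <- "kappa_NMDA.frontal.L"
  set.seed(56)
  groups <- rep(c("control", "encephalopathy", "nmdar"), c(6, 6, 8))
  post <- lapply(seq_along(groups), function(i) {
    m <- setNames(rnorm(length(labs), 0, 0.05), labs)
    if (groups[i] == "nmdar") m[target] <- m[target] - 0.4
    list(mean = m, cov = diag(0.04^2, length(labs)))
  })
  peb <- peb_fit(post, build_design(groups), parameters = labs)
  b <- peb$beta[target, "nmdar"]
  s <- peb$beta_sd[target, "nmdar"]
  expect_lt(abs(b - (-0.4)), 2 * s + 0.1)
  expect_lt(b, 0)
})

test_that("Bayesian model reduction matches a direct conjugate refit", {
  # 2-parameter linear-Gaussian toy: reduced evidence via bmr_delta_f must
  # equal the difference of directly computed evidences
  set.seed(57)
  n <- 20
  G <- matrix(rnorm(n * 2), n)
  beta <- c(0.7, 0)
  y <- as.numeric(G %*% beta) + rnorm(n, 0, 0.5)
  tau <- 4
  evidence <- function(v) {
    Sy <- G %*% diag(v) %*% t(G) + diag(1 / tau, n)
    -0.5 * (n * log(2 * pi) +
              as.numeric(determinant(Sy, logarithm = TRUE)$modulus) +
              sum(y * solve(Sy, y)))
  }
  v_full <- c(1, 1)
  v_red <- c(1, 1e-8)
  Pb <- tau * crossprod(G) + diag(1 / v_full)
  mb <- solve(Pb, tau * crossprod(G, y))
  d <- cmcEEG:::bmr_delta_f(Pb, mb, v_full, v_red)
  expect_equal(d$dF, evidence(v_red) - evidence(v_full), tolerance = 1e-8)
  # identity reduction changes nothing
  d0 <- cmcEEG:::bmr_delta_f(Pb, mb, v_full, v_full)
  expect_equal(d0$dF, 0, tolerance = 1e-10)
})

test_that("the effect search is selective and its probabilities monotone", {
  net <- fix_net()
  labs <- param_labels(net)
  effp <- names(default_group_effects()$nmdar)
  pt <- count_parameters(net)
  cls <- setNames(pt$classes, pt$labels)
  mk_cohort_post <- function(seed, effect) {
    set.seed(seed)
    groups <- rep(c("control", "encephalopathy", "nmdar"), c(6, 6, 8))
    post <- lapply(seq_along(groups), function(i) {
      m <- setNames(rnorm(length(labs), 0, 0.05), labs)
      if (groups[i] == "nmdar") m[effp] <- m[effp] + effect
      list(mean = m, cov = diag(0.05^2, length(labs)))
    })
    list(post = post, groups = groups)
  }
  # NMDA-selective detection across seeded replicates
  hits <- vapply(1:3, function(r) {
    cp <- mk_cohort_post(600 + r, -0.5)
    peb <- peb_fit(cp$post, build_design(cp$groups), parameters = labs)
    bmr <- bmr_search(peb)
    sig <- bmr$effects[bmr$effects$Pp > 0.95 &
                         bmr$effects$covariate == "nmdar", ]
    k <- table(factor(cls[sig$parameter], levels = names(pt$sets)))
    k[["NMDA"]] >= 1 && k[["AMPA"]] == 0 && k[["GABAA"]] == 0
  }, logical(1))
  expect_true(all(hits))
  # probabilities increase with the simulated effect size
  pp <- vapply(c(-0.1, -0.3, -0.6), function(es) {
    cp <- mk_cohort_post(700, es)
    peb <- peb_fit(cp$post, build_design(cp$groups), parameters = labs)
    bmr <- bmr_search(peb)
    mean(bmr$effects$Pp[bmr$effects$covariate == "nmdar" &
                          bmr$effects$parameter %in% effp])
  }, 0)
  expect_true(all(diff(pp) >= -0.02))
  expect_gt(pp[3], pp[1])
})

test_that("type-I error of the effect search is controlled", {
  r <- experiment_null_fp(n_rep = 8, seed = 9)
  expect_lte(r$fp_rate, 0.10)
})

test_that("classification thresholds the canonical axis and adjusts confounds", {
  set.seed(61)
  g <- factor(rep(c("nmdar", "encephalopathy"), each = 10))
  v <- c(1, -1, 0.5)
  Y <- matrix(rnorm(60, 0, 0.3), 20)
  Y[g == "nmdar", ] <- Y[g == "nmdar", ] +
    matrix(rep(2 * v, each = 10), 10)
  r <- classify(Y, v, g)
  expect_equal(r$accuracy, 1)
  # an alpha-driven perturbation in a minority of encephalitis subjects
  # pushes their scores across the boundary; regressing the measured
  # alpha power out restores them
  alpha <- exp(rnorm(20, log(5), 0.2))
  conf <- c(1:4, integer(0))
  alpha[conf] <- alpha[conf] + 25
  Yc <- Y
  Yc[conf, ] <- Yc[conf, ] - (alpha[conf] - 5) / 6 *
    matrix(rep(v, each = length(conf)), length(conf))
  r0 <- classify(Yc, v, g)
  r1 <- classify(Yc, v, g, alpha_power = alpha)
  expect_lt(r0$accuracy, 1)
  expect_gt(r1$accuracy, r0$accuracy)
  # degenerate inputs
  expect_error(classify(Y[1, , drop = FALSE], v, g[1]), "two classes")
  expect_error(classify(Y, v, g, alpha_power = c(alpha[-1], NA)),
               "complete")
})
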