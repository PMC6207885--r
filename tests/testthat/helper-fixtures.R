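# Shared fixtures built in code. Everything deterministic given the seeds.

fix_net <- function(...) build_default_network(...)

fix_lf <- function(net = fix_net()) make_lead_field(net)

# orthonormal 8-mode matrix spanning the lead field plus random complements
fix_modes <- function(lf, seed = 1) {
  set.seed(seed)
  qr.Q(qr(cbind(lf$gain, matrix(rnorm(nrow(lf$gain) * 4),
                                nrow(lf$gain)))))[, 1:8]
}

fix_fwd <- function(freqs = 2:6, net = fix_net(), lf = fix_lf(net),
                    modes = fix_modes(lf), ...) {
  forward_model(net, lf, modes, freqs, ...)
}

# linear-Gaussian toy: y = A theta + e, theta ~ N(m0, C0), e ~ N(0, I/tau)
# with closed-form evidence and posterior
toy_linear <- function(n = 12, p = 3, tau = 4, seed = 42) {
  set.seed(seed)
  A <- matrix(rnorm(n * p), n)
  m0 <- rnorm(p, 0, 0.5)
  C0 <- diag(runif(p, 0.2, 1))
  theta <- m0 + as.numeric(chol(C0) %*% rnorm(p))
  y <- as.numeric(A %*% theta) + rnorm(n, 0, 1 / sqrt(tau))
  Sy <- A %*% C0 %*% t(A) + diag(1 / tau, n)
  r <- y - as.numeric(A %*% m0)
  logZ <- -0.5 * (n * log(2 * pi) +
                    as.numeric(determinant(Sy, logarithm = TRUE)$modulus) +
                    sum(r * solve(Sy, r)))
  P_post <- t(A) %*% A * tau + solve(C0)
  m_post <- solve(P_post, tau * t(A) %*% y + solve(C0, m0))
  list(A = A, y = y, tau = tau, logZ = logZ,
       priors = list(mean = m0, cov = C0),
       post_mean = as.numeric(m_post), post_cov = solve(P_post))
}

# hand-rolled 4x4 characteristic polynomial coefficients (for the
# brute-force eigenvalue oracle)
charpoly4 <- function(M) {
  stopifnot(all(dim(M) == c(4, 4)))
  # coefficients of det(xI - M) = x^4 + c3 x^3 + c2 x^2 + c1 x + c0
  tr1 <- sum(diag(M))
  M2 <- M %*% M
  tr2 <- sum(diag(M2))
  M3 <- M2 %*% M
  tr3 <- sum(diag(M3))
  M4 <- M3 %*% M
  tr4 <- sum(diag(M4))
  c3 <- -tr1
  c2 <- (tr1^2 - tr2) / 2
  c1 <- -(tr1^3 - 3 * tr1 * tr2 + 2 * tr3) / 6
  c0 <- (tr1^4 - 6 * tr1^2 * tr2 + 3 * tr2^2 + 8 * tr1 * tr3 -
           6 * tr4) / 24
  c(c0, c1, c2, c3, 1)
}

# numeric gradient of a scalar/vector function (independent oracle)
fd_jacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

# quick synthetic recording: white noise plus optional sinusoids, uV scale
fix_recording <- function(duration = 60, rate = 250, seed = 7, amp = 10) {
  set.seed(seed)
  n <- duration * rate
  x <- t(sapply(1:21, function(i) {
    z <- as.numeric(stats::filter(rnorm(n), 0.9, "recursive"))
    z / sd(z) * amp
  }))
  recording(x, rate)
}
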