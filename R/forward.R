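#' Forward model: parameters to sensor-mode cross-spectra
#'
#' Bundles everything needed to map a free-parameter vector to a predicted
#' sensor-mode cross-spectral density: the network, lead field, spatial
#' modes, frequency grid and the observation-noise model. The heavy lifting
#' (fixed point, analytic Jacobian, delay compensation, transfer functions)
#' runs in compiled code.
#'
#' @param net A `cmc_network`.
#' @param lf A `lead_field` (see [make_lead_field()]).
#' @param modes Channel x mode matrix with orthonormal columns.
#' @param freqs Frequency grid, Hz.
#' @param constants Constant set, by default [cmc_constants()].
#' @return Object of class `cmc_forward`.
#' @export
forward_model <- function(net, lf, modes, freqs,
                          constants = cmc_constants(),
                          exact_delays = TRUE) {
  L <- lf$gain
  stopifnot(nrow(modes) == nrow(L))
  nsrc <- length(net$sources)
  n <- 16L * nsrc
  pw <- lf$pop_weights[constants$populations]
  Lpop <- matrix(0, nrow(L), n)
  for (s in seq_len(nsrc))
    for (p in 1:4)
      Lpop[, state_index(s, p, 1L)] <- L[, s] * pw[p]
  Out <- t(modes) %*% Lpop
  B <- matrix(0, n, nsrc)
  for (s in seq_len(nsrc)) B[state_index(s, 1L, 1L), s] <- 1 / constants$C
  structure(list(net = net, lf = lf, modes = modes,
                 freqs = as.numeric(freqs), Out = Out, B = B,
                 constants = constants, exact_delays = exact_delays,
                 cache = new.env(parent = emptyenv()),
                 labels = c(param_labels(net), noise_labels())),
            class = "cmc_forward")
}

# 1-based flat state index: source s, population p (SS,SP,II,DP), state st
# (V, gAMPA, gGABAA, gNMDA)
state_index <- function(s, p, st) (s - 1L) * 16L + (p - 1L) * 4L + st

default_x0 <- function(ctx) {
  x0 <- rep(c(ctx$VL + ctx$bg / ctx$gL, 0, 0, 0), 4L * ctx$nsrc)
  x0
}

#' Find the fixed point of the network dynamics
#'
#' Damped Newton iteration (with a short relaxation-integration fallback) on
#' the assembled vector field, using the analytic Jacobian.
#'
#' @inheritParams resolve_params
#' @param x0 Starting state; defaults to the leak-balance resting state.
#' @param tol Convergence tolerance on the max-norm of the derivatives.
#' @param maxit Maximum Newton iterations.
#' @return Numeric state vector with attributes `residual` and `iterations`.
#' @export
find_fixed_point <- function(lambda = NULL, net = build_default_network(),
                             x0 = NULL, tol = 1e-8, maxit = 100,
                             constants = cmc_constants()) {
  ctx <- resolve_params(lambda, net, constants)$ctx
  if (is.null(x0)) x0 <- default_x0(ctx)
  fp <- .cmc_fixed_point(ctx, x0, tol, maxit, 4000L)
  if (!fp$converged)
    stop("fixed-point search did not converge: residual ", fp$residual,
         " after ", fp$iterations, " iterations")
  structure(as.numeric(fp$x), residual = fp$residual,
            iterations = fp$iterations)
}

#' Linearize the network about its fixed point
#'
#' Returns the fixed point, the analytic Jacobian, and the delay-compensated
#' Jacobian `(I - D o J)^-1 J` in which `D` holds the pairwise transmission
#' delays (the intra-source delay between distinct populations of a source,
#' the fixed inter-source delay across sources).
#'
#' @inheritParams find_fixed_point
#' @return List with `x`, `J`, `Jd`, `eigenvalues`, `max_real` and `ctx`.
#' @export
linearize <- function(lambda = NULL, net = build_default_network(),
                      x0 = NULL, tol = 1e-8,
                      constants = cmc_constants()) {
  ctx <- resolve_params(lambda, net, constants)$ctx
  x <- find_fixed_point(lambda, net, x0 = x0, tol = tol,
                        constants = constants)
  J <- .cmc_jacobian(ctx, as.numeric(x))
  D <- .cmc_delay_matrix(ctx)
  Jd <- solve(diag(nrow(J)) - D * J, J)
  ev <- eigen(Jd, only.values = TRUE)$values
  list(x = as.numeric(x), J = J, Jd = Jd, eigenvalues = ev,
       max_real = max(Re(ev)), ctx = ctx)
}

#' Transfer functions of a linearized system
#'
#' `H(f) = Out (i 2 pi f I - Jd)^-1 B` per frequency, with the Jacobian in
#' ms^-1 units and `f` in Hz.
#'
#' @param lin A linearized system from [linearize()].
#' @param freqs Frequency grid, Hz.
#' @param Out Observation matrix (rows x states); any linear read-out.
#' @param B Input matrix (states x inputs).
#' @return Complex array `n_out x n_in x n_freq`.
#' @export
transfer_functions <- function(lin, freqs, Out, B) {
  if (lin$max_real >= 0)
    stop_unstable(lin$max_real)
  n <- nrow(lin$Jd)
  H <- array(0i, c(nrow(Out), ncol(B), length(freqs)))
  for (k in seq_along(freqs)) {
    w <- 2 * pi * freqs[k] / 1000
    H[, , k] <- Out %*% solve(1i * w * diag(n) - lin$Jd, B)
  }
  H
}

stop_unstable <- function(max_real) {
  stop(structure(class = c("cmcEEG_unstable", "error", "condition"),
                 list(message = paste0(
                   "linearized system is unstable (max eigenvalue real part ",
                   signif(max_real, 4), " >= 0)"),
                   call = sys.call(-1), max_real = max_real)))
}

# innovations power spectral density on the grid
innovations_psd <- function(noise, freqs) {
  noise$u_amp^2 * pmax(freqs, 1e-6)^(-noise$u_exp)
}

#' Predicted sensor-mode cross-spectral density
#'
#' Evaluates `S(f) = H(f) G_u(f) H(f)^H` from the delay-compensated
#' linearization, where the innovations (a white-to-power-law current
#' entering the spiny stellate populations) have spectral density
#' `u_amp^2 f^(-u_exp)`, then adds channel-noise terms and returns the
#' Hermitian mode-space density.
#'
#' @param lambda Named vector of free parameters (neuronal log-scaling
#'   factors and noise parameters; missing entries are 0).
#' @param fwd A `cmc_forward` model.
#' @return A `cross_spectra` with attributes `fixed_point`, `eigenvalues`
#'   and `noise`.
#' @export
predicted_csd <- function(lambda = NULL, fwd) {
  rp <- resolve_params(lambda, fwd$net, fwd$constants)
  gu <- innovations_psd(rp$noise, fwd$freqs)
  warm <- !is.null(fwd$cache) && !is.null(fwd$cache$x)
  x0 <- if (warm) fwd$cache$x else default_x0(rp$ctx)
  pr <- .cmc_predict(rp$ctx, fwd$freqs, fwd$Out, fwd$B, gu,
                     x0, 1e-8, 100, fwd$exact_delays,
                     if (warm) 50L else 4000L)
  if (warm && pr$status != "ok") {
    # cold restart in case the cached state belongs to a different basin
    pr <- .cmc_predict(rp$ctx, fwd$freqs, fwd$Out, fwd$B, gu,
                       default_x0(rp$ctx), 1e-8, 100, fwd$exact_delays,
                       4000L)
  }
  if (pr$status == "unstable") stop_unstable(pr$max_real)
  if (pr$status != "ok")
    stop("forward prediction failed: ", pr$status)
  if (!is.null(fwd$cache)) fwd$cache$x <- as.numeric(pr$x)
  S <- pr$csd
  nm <- dim(S)[1]
  cn <- rp$noise$c_amp^2 + rp$noise$s_amp^2
  for (k in seq_along(fwd$freqs))
    S[, , k] <- S[, , k] + diag(cn, nm)
  out <- cross_spectra(fwd$freqs, S, tol = 1e-6)
  attr(out, "fixed_point") <- as.numeric(pr$x)
  attr(out, "eigenvalues") <- pr$eigenvalues
  attr(out, "noise") <- rp$noise
  out
}

#' Percent variance explained by a predicted cross-spectrum
#'
#' The squared Pearson correlation (x100) between the absolute values of the
#' predicted and observed cross-spectral matrices, concatenated over all
#' entries and frequencies.
#'
#' @param predicted,observed `cross_spectra` on the same grid.
#' @return Percent variance explained in `[0, 100]`.
#' @export
fit_variance_explained <- function(predicted, observed) {
  if (length(predicted$freqs) != length(observed$freqs) ||
      max(abs(predicted$freqs - observed$freqs)) > 1e-9)
    stop("frequency grids differ")
  if (!all(dim(predicted$S) == dim(observed$S)))
    stop("mode counts differ")
  a <- as.numeric(Mod(predicted$S))
  b <- as.numeric(Mod(observed$S))
  if (sd(a) == 0 || sd(b) == 0)
    stop("correlation undefined for constant cross-spectral vectors")
  100 * stats::cor(a, b)^2
}
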