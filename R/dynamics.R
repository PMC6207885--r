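#' Power spectrum of a single neuronal population
#'
#' Transfer-function spectrum of one population's activity (membrane
#' potential by default, or firing rate via the local sigmoid slope),
#' bypassing the lead field entirely — so the spectral output of the
#' inhibitory interneurons is available even though their dendritic
#' geometry contributes nothing to scalp EEG.
#'
#' @inheritParams resolve_params
#' @param population One of `"SS"`, `"SP"`, `"II"`, `"DP"`.
#' @param freqs Frequency grid, Hz.
#' @param measure `"voltage"` or `"rate"` (voltage scaled by the firing
#'   sigmoid's local slope at the fixed point).
#' @param noise Innovations spectrum parameters as resolved from `lambda`
#'   (the `noise.*` entries).
#' @return Data frame with `freq` and `power` (summed over sources).
#' @export
population_spectrum <- function(lambda = NULL,
                                net = build_default_network(),
                                population = "II",
                                freqs = seq(2, 48, by = 1),
                                measure = c("voltage", "rate"),
                                constants = cmc_constants()) {
  measure <- match.arg(measure)
  pops <- constants$populations
  p <- match(population, pops)
  if (is.na(p)) stop("unknown population: ", population)
  rp <- resolve_params(lambda, net, constants)
  lin <- linearize(lambda, net, constants = constants)
  nsrc <- length(net$sources)
  n <- 16L * nsrc
  Out <- matrix(0, nsrc, n)
  for (s in seq_len(nsrc)) {
    gain <- 1
    if (measure == "rate") {
      v <- lin$x[state_index(s, p, 1L)]
      sg <- rp$ctx$sigma
      r <- stats::plogis((v - rp$ctx$VR) / sg)
      gain <- r * (1 - r) / sg
    }
    Out[s, state_index(s, p, 1L)] <- gain
  }
  B <- matrix(0, n, nsrc)
  for (s in seq_len(nsrc)) B[state_index(s, 1L, 1L), s] <- 1 / rp$ctx$C
  H <- transfer_functions(lin, freqs, Out, B)
  gu <- innovations_psd(rp$noise, freqs)
  pow <- vapply(seq_along(freqs), function(k)
    sum(Mod(H[, , k])^2) * gu[k], 0)
  data.frame(freq = freqs, power = pow)
}

#' Stability analysis of the fitted dynamics
#'
#' Full eigen-decomposition of the delay-compensated Jacobian at the fixed
#' point. The maximum eigenvalue real part measures the distance from
#' dynamical instability (values approaching zero indicate a system closer
#' to oscillatory runaway); imaginary parts give the natural oscillation
#' frequencies.
#'
#' @inheritParams resolve_params
#' @return Object of class `stability_report`: `eigenvalues`, `max_real`
#'   (ms^-1), and `frequencies` (Hz, non-negative).
#' @export
stability_eigenspectrum <- function(lambda = NULL,
                                    net = build_default_network(),
                                    constants = cmc_constants()) {
  lin <- linearize(lambda, net, constants = constants)
  structure(list(eigenvalues = lin$eigenvalues,
                 max_real = lin$max_real,
                 frequencies = abs(Im(lin$eigenvalues)) * 1000 / (2 * pi),
                 n_states = length(lin$eigenvalues)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report:", x$n_states, "eigenvalues | max Re =",
      signif(x$max_real, 4), "ms^-1 | dominant oscillation",
      round(x$frequencies[which.max(Re(x$eigenvalues))], 1), "Hz\n")
  invisible(x)
}
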