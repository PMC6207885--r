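#' Presynaptic firing rate
#'
#' Expected proportion of an ensemble firing at membrane potential `V`: a
#' logistic sigmoid of the depolarization relative to threshold, with slope
#' set by the ensemble firing variance (larger dispersion of thresholds
#' across the ensemble flattens the population activation curve).
#'
#' @param V Membrane potential, mV (vectorized).
#' @param threshold Threshold potential, mV.
#' @param variance Ensemble firing variance, mV^2 (> 0).
#' @return Firing rate in (0, 1), strictly increasing in `V`.
#' @export
presynaptic_rate <- function(V, threshold = cmc_constants()$VR,
                             variance = cmc_constants()$sigma2) {
  if (!is.numeric(variance) || length(variance) != 1L || variance <= 0)
    stop("ensemble firing `variance` must be a positive scalar")
  stats::plogis((V - threshold) / sqrt(variance))
}

#' Magnesium-block gain of the NMDA channel
#'
#' Voltage-dependent relief of the magnesium block, modelled as the
#' three-parameter sigmoid `alpha / (1 + beta * exp(-gamma * V))`: near the
#' resting potential most NMDA channels are blocked; depolarization releases
#' the block and the gain saturates at `alpha`.
#'
#' @param V Membrane potential, mV (vectorized).
#' @param mg Named vector or list with `alpha`, `beta`, `gamma` (all > 0).
#' @return Gain in (0, alpha), strictly increasing in `V`.
#' @export
mg_block_gain <- function(V, mg = cmc_constants()$mg) {
  mg <- unlist(mg)[c("alpha", "beta", "gamma")]
  if (any(!is.finite(mg)) || any(mg <= 0))
    stop("magnesium-block parameters alpha, beta, gamma must all be > 0")
  mg[["alpha"]] / (1 + mg[["beta"]] * exp(-mg[["gamma"]] * V))
}

#' Single-population state derivatives
#'
#' Reference implementation of the four state equations of one neuronal
#' population: a capacitive membrane equation driven by leak, AMPA, GABA-A
#' and magnesium-gated NMDA channel currents plus background (and exogenous)
#' current, and first-order kinetics for the three channel conductances
#' relaxing towards the coupling-weighted presynaptic drive at the receptor's
#' rate constant.
#'
#' @param state Numeric vector `c(V, gAMPA, gGABAA, gNMDA)`.
#' @param presyn Named vector of non-negative presynaptic drives
#'   `c(AMPA=, GABAA=, NMDA=)` (already coupling-weighted).
#' @param sp Source parameters: list with `kappa` (named rate constants,
#'   ms^-1), `gL`, `VL`, `C`, `bg`; defaults from [cmc_constants()].
#' @param mg Magnesium-block parameters, as in [mg_block_gain()].
#' @param exogenous Additional current entering the membrane equation.
#' @return Numeric vector `d(state)/dt` (per ms).
#' @export
population_derivatives <- function(state, presyn, sp = NULL,
                                   mg = cmc_constants()$mg, exogenous = 0) {
  k <- cmc_constants()
  if (is.null(sp))
    sp <- list(kappa = 1 / k$tau, gL = k$gL, VL = k$VL, C = k$C, bg = k$bg)
  if (any(presyn < 0)) stop("presynaptic drives must be non-negative")
  if (length(state) != 4L) stop("state must be (V, gAMPA, gGABAA, gNMDA)")
  V <- state[1]; g <- state[2:4]
  rev <- k$rev[c("AMPA", "GABAA", "NMDA")]
  gate <- c(1, 1, mg_block_gain(V, mg))
  i_chan <- sum(g * gate * (rev - V))
  dV <- (sp$gL * (sp$VL - V) + i_chan + sp$bg + exogenous) / sp$C
  kap <- sp$kappa[c("AMPA", "GABAA", "NMDA")]
  dg <- kap * (presyn[c("AMPA", "GABAA", "NMDA")] - g)
  unname(c(dV, dg))
}

#' Default prior density over the model parameters
#'
#' Prior means sit at the physiological values in [cmc_constants()] (channel
#' time constants of 12, 8 and 100 ms for AMPA, GABA-A and NMDA; reversal
#' potentials 60, 10 and -70 mV for the sodium, calcium and chloride
#' carriers) under the log-normal scaling convention: each free parameter
#' multiplies its prior mean by `exp(lambda)` with `lambda ~ N(0, v)`. The
#' returned density covers the neuronal parameters plus the observation-noise
#' parameters.
#'
#' @param net A `cmc_network`.
#' @param prior_variance Prior variance of the neuronal log-scaling factors
#'   (scalar, or named vector overriding individual labels).
#' @param noise_variance Prior variances for the three noise parameters.
#' @return Object of class `prior_density`: list with `mean`, `cov`,
#'   `labels`, and `partition`.
#' @export
default_priors <- function(net = build_default_network(),
                           prior_variance = 1 / 16,
                           noise_variance = c(1 / 2, 1 / 8, 1 / 2)) {
  labels <- c(param_labels(net), noise_labels())
  v <- setNames(rep(1 / 16, length(labels)), labels)
  if (is.null(names(prior_variance))) {
    v[] <- prior_variance[1]
  } else {
    unknown <- setdiff(names(prior_variance), labels)
    if (length(unknown))
      stop("unknown parameter labels: ", paste(unknown, collapse = ", "))
    v[names(prior_variance)] <- prior_variance
  }
  v[noise_labels()] <- noise_variance
  structure(list(
    mean = setNames(numeric(length(labels)), labels),
    cov = diag(unname(v), length(labels)),
    labels = labels,
    partition = count_parameters(param_labels(net))
  ), class = "prior_density")
}

#' @export
print.prior_density <- function(x, ...) {
  cat("prior_density over", length(x$labels), "log-scale parameters\n")
  invisible(x)
}

#' Read or write a labeled parameter vector
#'
#' Flat serialization of a (log-scale) parameter vector with canonical
#' labels, as CSV (`label,value`) or JSON depending on the file extension.
#'
#' @param lambda Named numeric vector.
#' @param path Output path (`.csv` or `.json`).
#' @return `write_params` returns `path` invisibly; `read_params` the named
#'   vector.
#' @export
write_params <- function(lambda, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(lambda), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    write.csv(data.frame(label = names(lambda), value = unname(lambda)),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (grepl("\\.json$", path)) {
    unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    d <- read.csv(path, stringsAsFactors = FALSE)
    setNames(d$value, d$label)
  }
}
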