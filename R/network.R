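#' Build the fronto-parietal source network
#'
#' The default network has four sources at fixed MNI coordinates: left and
#' right parietal at (-29, -68, 49) / (29, -68, 49) and left and right
#' prefrontal at (-33, 45, 28) / (33, 45, 28). Superficial pyramidal cells of
#' the parietal sources send forward (feedforward) connections to the spiny
#' stellate and deep pyramidal populations of the ipsilateral frontal source;
#' deep pyramidal cells of the frontal sources send backward (feedback)
#' connections to the superficial pyramidal and inhibitory interneuron
#' populations of the ipsilateral parietal source. Homologous sources are
#' linked interhemispherically (superficial pyramidal to superficial
#' pyramidal) with weights fixed at their prior values.
#'
#' @param include_sp_to_ss Add the model-variant intra-source NMDA-bearing
#'   interconnection from superficial pyramidal to spiny stellate cells.
#' @param hemispheres Hemispheres to include; `c("L", "R")` gives the default
#'   four-source network, a single hemisphere gives a reduced two-source
#'   configuration.
#' @return An object of class `cmc_network`.
#' @export
build_default_network <- function(include_sp_to_ss = FALSE,
                                  hemispheres = c("L", "R")) {
  hemispheres <- match.arg(hemispheres, c("L", "R"), several.ok = TRUE)
  nodes <- data.frame(
    name = c("parietal.L", "parietal.R", "frontal.L", "frontal.R"),
    x = c(-29, 29, -33, 33),
    y = c(-68, -68, 45, 45),
    z = c(49, 49, 28, 28),
    hemisphere = c("L", "R", "L", "R"),
    role = c("parietal", "parietal", "frontal", "frontal"),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[nodes$hemisphere %in% hemispheres, , drop = FALSE]
  rownames(nodes) <- NULL
  forward <- backward <- lateral <- NULL
  for (h in hemispheres) {
    par <- nodes$name[nodes$role == "parietal" & nodes$hemisphere == h]
    fro <- nodes$name[nodes$role == "frontal" & nodes$hemisphere == h]
    forward <- rbind(forward, data.frame(
      from = par, from_pop = "SP", to = c(fro, fro),
      to_pop = c("SS", "DP"), hemisphere = h, stringsAsFactors = FALSE))
    backward <- rbind(backward, data.frame(
      from = fro, from_pop = "DP", to = c(par, par),
      to_pop = c("SP", "II"), hemisphere = h, stringsAsFactors = FALSE))
  }
  if (length(hemispheres) == 2L) {
    for (role in c("parietal", "frontal")) {
      pair <- nodes$name[nodes$role == role]
      lateral <- rbind(lateral, data.frame(
        from = pair, from_pop = "SP", to = rev(pair), to_pop = "SP",
        stringsAsFactors = FALSE))
    }
  }
  structure(list(nodes = nodes, sources = nodes$name,
                 hemispheres = hemispheres,
                 forward = forward, backward = backward, lateral = lateral,
                 include_sp_to_ss = include_sp_to_ss),
            class = "cmc_network")
}

#' @export
print.cmc_network <- function(x, ...) {
  cat("cmc_network:", length(x$sources), "sources (",
      paste(x$sources, collapse = ", "), ")\n")
  cat("  forward edges:", nrow(x$forward),
      "| backward edges:", nrow(x$backward),
      "| interhemispheric links:",
      if (is.null(x$lateral)) 0L else nrow(x$lateral), "\n")
  cat("  SP->SS NMDA variant:", x$include_sp_to_ss, "\n")
  invisible(x)
}

#' Serialize / restore a network description
#'
#' @param net A `cmc_network`.
#' @param path File path for the JSON description.
#' @return `write_network` returns `path` invisibly; `read_network` returns a
#'   `cmc_network`.
#' @export
write_network <- function(net, path) {
  jsonlite::write_json(
    list(nodes = net$nodes, hemispheres = net$hemispheres,
         include_sp_to_ss = net$include_sp_to_ss),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_default_network(include_sp_to_ss = isTRUE(d$include_sp_to_ss),
                        hemispheres = d$hemispheres)
}

#' Canonical labels of the free neuronal parameters
#'
#' Each label names one log-scaling factor on a prior mean. For the default
#' four-source network there are exactly 41: 12 rate constants (three
#' receptors x four sources), 12 intrinsic coupling weights (three receptors x
#' four sources, the NMDA entry acting on excitatory targets), 4 separate
#' NMDA weights onto inhibitory interneurons (one per source), 2 forward and
#' 2 backward extrinsic AMPA weights (one per hemisphere), the ensemble
#' firing variance, the background current, 4 intra-source delays and the 3
#' magnesium-block parameters.
#'
#' @param net A `cmc_network`.
#' @return Character vector of parameter labels.
#' @export
param_labels <- function(net) {
  src <- net$sources
  hemi <- net$hemispheres
  c(paste0("kappa_AMPA.", src),
    paste0("kappa_GABAA.", src),
    paste0("kappa_NMDA.", src),
    paste0("w_AMPA.", src),
    paste0("w_GABAA.", src),
    paste0("w_NMDA_E.", src),
    paste0("w_NMDA_I.", src),
    paste0("fwd.", hemi),
    paste0("bwd.", hemi),
    "firing_var", "background",
    paste0("delay.", src),
    "mg.alpha", "mg.beta", "mg.gamma")
}

#' Labels of the observation-model (noise) parameters
#'
#' Kept outside the neuronal parameter set: log-amplitude of the innovations
#' driving the spiny stellate populations, an additive shift on the
#' innovations spectral exponent, and the log-amplitude of channel noise.
#'
#' @return Character vector of noise parameter labels.
#' @export
noise_labels <- function() c("noise.u_amp", "noise.u_exp", "noise.c_amp")

#' Partition the neuronal parameters into receptor classes
#'
#' Splits the flat neuronal parameter vector into disjoint NMDA, AMPA, GABA-A
#' and other index sets. For the default network the sizes are 15 / 12 / 8 /
#' 6 (41 parameters in total): NMDA = 4 rate constants + 4 weights onto
#' excitatory targets + 4 weights onto inhibitory interneurons + 3
#' magnesium-block parameters; AMPA = 4 rate constants + 4 intrinsic weights
#' + 2 forward + 2 backward extrinsic weights; GABA-A = 4 rate constants + 4
#' intrinsic weights; other = firing variance, background current and 4
#' delays.
#'
#' @param net A `cmc_network` (or a character vector of labels).
#' @return Object of class `param_partition`: list with `sets` (named index
#'   lists), `sizes`, `total` and `labels`.
#' @export
count_parameters <- function(net) {
  labels <- if (is.character(net)) net else param_labels(net)
  cls <- function(l) {
    if (grepl("^(kappa_NMDA|w_NMDA_E|w_NMDA_I|mg)\\.", l)) "NMDA"
    else if (grepl("^(kappa_AMPA|w_AMPA|fwd|bwd)\\.", l)) "AMPA"
    else if (grepl("^(kappa_GABAA|w_GABAA)\\.", l)) "GABAA"
    else "OTHER"
  }
  classes <- vapply(labels, cls, character(1))
  sets <- lapply(c(NMDA = "NMDA", AMPA = "AMPA", GABAA = "GABAA",
                   OTHER = "OTHER"),
                 function(k) which(classes == k))
  structure(list(sets = sets, sizes = vapply(sets, length, integer(1)),
                 total = length(labels), labels = labels,
                 classes = unname(classes)),
            class = "param_partition")
}

#' @export
print.param_partition <- function(x, ...) {
  cat("param_partition:", x$total, "neuronal parameters (",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Resolve log-scale parameters into the numeric model context
#'
#' Applies the log-normal scaling convention: every free neuronal parameter
#' multiplies its prior mean by `exp(lambda)`. Returns the fully numeric
#' context consumed by the compiled vector field, plus resolved observation
#' noise parameters.
#'
#' @param lambda Named numeric vector of log-scaling factors (missing entries
#'   are treated as 0); names as in [param_labels()] / [noise_labels()].
#' @param net A `cmc_network`.
#' @param constants Constant set, by default [cmc_constants()].
#' @return List with elements `ctx` (compiled-core context), `noise`
#'   (resolved noise parameters) and `labels`.
#' @export
resolve_params <- function(lambda = NULL, net = build_default_network(),
                           constants = cmc_constants()) {
  k <- constants
  labels <- param_labels(net)
  full <- setNames(numeric(length(labels) + 3L), c(labels, noise_labels()))
  if (!is.null(lambda)) {
    if (is.null(names(lambda)))
      stop("`lambda` must be a named vector of log-scaling factors")
    unknown <- setdiff(names(lambda), names(full))
    if (length(unknown))
      stop("unknown parameter labels: ", paste(unknown, collapse = ", "))
    full[names(lambda)] <- lambda
  }
  src <- net$sources
  nsrc <- length(src)
  pops <- k$populations
  pidx <- setNames(seq_along(pops), pops)

  kappa <- matrix(0, nsrc, 3)
  for (i in seq_len(nsrc)) {
    kappa[i, 1] <- exp(full[paste0("kappa_AMPA.", src[i])]) / k$tau["AMPA"]
    kappa[i, 2] <- exp(full[paste0("kappa_GABAA.", src[i])]) / k$tau["GABAA"]
    kappa[i, 3] <- exp(full[paste0("kappa_NMDA.", src[i])]) / k$tau["NMDA"]
  }

  put <- function(W, spec, scale) {
    for (nm in names(spec)) {
      pq <- strsplit(nm, "_", fixed = TRUE)[[1]]
      W[pidx[toupper(pq[1])], pidx[toupper(pq[2])]] <-
        spec[[nm]] * scale
    }
    W
  }
  WA <- array(0, c(4, 4, nsrc)); WG <- WA; WN <- WA
  for (i in seq_len(nsrc)) {
    WA[, , i] <- put(matrix(0, 4, 4), k$w_ampa,
                     exp(full[paste0("w_AMPA.", src[i])]))
    WG[, , i] <- put(matrix(0, 4, 4), k$w_gaba,
                     exp(full[paste0("w_GABAA.", src[i])]))
    Wn <- put(matrix(0, 4, 4), k$w_nmda_e,
              exp(full[paste0("w_NMDA_E.", src[i])]))
    Wn <- put(Wn, k$w_nmda_i, exp(full[paste0("w_NMDA_I.", src[i])]))
    if (isTRUE(net$include_sp_to_ss))
      Wn[pidx["SS"], pidx["SP"]] <-
        k$w_spss_nmda * exp(full[paste0("w_NMDA_E.", src[i])])
    WN[, , i] <- Wn
  }

  sidx <- setNames(seq_len(nsrc), src)
  edge_rows <- list()
  add_edges <- function(df, w) {
    if (is.null(df)) return()
    for (r in seq_len(nrow(df))) {
      edge_rows[[length(edge_rows) + 1L]] <<- c(
        sidx[df$from[r]] - 1L, pidx[df$from_pop[r]] - 1L,
        sidx[df$to[r]] - 1L, pidx[df$to_pop[r]] - 1L, 0L,  # AMPA-mediated
        w[r])
    }
  }
  if (!is.null(net$forward))
    add_edges(net$forward,
              k$w_fwd * exp(full[paste0("fwd.", net$forward$hemisphere)]))
  if (!is.null(net$backward))
    add_edges(net$backward,
              k$w_bwd * exp(full[paste0("bwd.", net$backward$hemisphere)]))
  if (!is.null(net$lateral))   # fixed at prior value, not free
    add_edges(net$lateral, rep(k$w_lat, nrow(net$lateral)))
  if (length(edge_rows)) {
    em <- do.call(rbind, edge_rows)
    edges <- matrix(as.integer(em[, 1:5]), ncol = 5)
    ew <- as.numeric(em[, 6])
  } else {
    edges <- matrix(integer(0), 0, 5)
    ew <- numeric(0)
  }

  ctx <- list(
    nsrc = nsrc,
    kappa = kappa,
    WA = WA, WG = WG, WN = WN,
    edges = edges, ew = ew,
    mg = unname(k$mg * exp(full[c("mg.alpha", "mg.beta", "mg.gamma")])),
    VR = k$VR,
    sigma = sqrt(k$sigma2 * exp(full["firing_var"])),
    rev = unname(k$rev[c("AMPA", "GABAA", "NMDA")]),
    VL = k$VL, gL = k$gL, C = k$C,
    bg = k$bg * exp(full["background"]),
    delays = unname(k$delay_intra *
                      exp(full[paste0("delay.", src)])),
    dext = k$delay_ext
  )
  noise <- list(
    u_amp = exp(full["noise.u_amp"]),
    u_exp = 0 + full["noise.u_exp"],
    c_amp = 0.005 * exp(full["noise.c_amp"]),
    s_amp = 0
  )
  list(ctx = ctx, noise = lapply(noise, unname), labels = labels)
}

#' Assemble the network state equations
#'
#' Builds the global vector field and its analytic Jacobian for a parameter
#' setting. The default four-source network has 64 states (4 sources x 4
#' populations x 4 states). Extrinsic connections enter as additional
#' presynaptic drive on the target populations' AMPA (and, for the model
#' variant, NMDA) conductance equations; inter-source delays act through the
#' delay-compensated Jacobian.
#'
#' @inheritParams resolve_params
#' @return List with `f(x)` (derivatives), `jacobian(x)` (analytic),
#'   `n_states` and the resolved `ctx`.
#' @export
assemble_state_equations <- function(net = build_default_network(),
                                     lambda = NULL,
                                     constants = cmc_constants()) {
  ctx <- resolve_params(lambda, net, constants)$ctx
  list(
    f = function(x) as.numeric(.cmc_rhs(ctx, x)),
    jacobian = function(x) .cmc_jacobian(ctx, x),
    n_states = 16L * ctx$nsrc,
    ctx = ctx
  )
}

#' Synthetic lead field
#'
#' Gain matrix mapping the four sources to scalp channels. The paper-grade
#' finite-element lead field requires subject anatomy; here a seeded random
#' gain matrix with unit-norm columns stands in (only the mixing structure
#' matters for the pipeline). Population contribution weights are
#' superficial-pyramidal dominant and exactly zero for inhibitory
#' interneurons, whose dendritic arborization does not generate a scalp
#' dipole.
#'
#' @param net A `cmc_network`.
#' @param n_channels Number of channels (default 21, the 10-20 montage).
#' @param seed RNG seed for the gain matrix.
#' @param pop_weights Population contribution weights (SS, SP, II, DP).
#' @return Object of class `lead_field`: list with `gain` (n_channels x
#'   n_sources), `pop_weights` and `channels`.
#' @export
make_lead_field <- function(net = build_default_network(), n_channels = 21,
                            seed = 8601,
                            pop_weights = cmc_constants()$pop_weights) {
  stopifnot(pop_weights["II"] == 0)
  ch <- montage_1020()
  if (n_channels != length(ch)) ch <- paste0("ch", seq_len(n_channels))
  L <- withr_seed(seed, {
    m <- matrix(rnorm(n_channels * length(net$sources)), n_channels)
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  })
  colnames(L) <- net$sources
  rownames(L) <- ch
  structure(list(gain = L, pop_weights = pop_weights, channels = ch),
            class = "lead_field")
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Standard 10-20 montage channel labels (21 channels)
#' @return Character vector of channel names.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "O2", "A1", "A2")
}

#' Project a source-space cross-spectral density to sensor modes
#'
#' Computes `t(M) L S(f) t(L) M` per frequency, where `L` is the lead-field
#' gain (already combining population weights upstream) and `M` holds
#' orthonormal spatial modes over channels. The output is re-Hermitianized
#' against floating-point drift.
#'
#' @param source_csd Complex array n_sources x n_sources x n_freq.
#' @param lf A `lead_field`.
#' @param modes Channel x mode matrix with orthonormal columns.
#' @param freqs Frequency grid (Hz) attached to the result.
#' @return A `cross_spectra` object (modes x modes x n_freq).
#' @export
project_to_sensors <- function(source_csd, lf, modes, freqs = NULL) {
  L <- if (inherits(lf, "lead_field")) lf$gain else lf
  stopifnot(nrow(modes) == nrow(L), dim(source_csd)[1] == ncol(L))
  P <- t(Conj(modes)) %*% L
  nf <- dim(source_csd)[3]
  out <- array(0i, c(ncol(modes), ncol(modes), nf))
  for (i in seq_len(nf)) {
    S <- P %*% source_csd[, , i] %*% t(Conj(P))
    out[, , i] <- (S + t(Conj(S))) / 2
  }
  if (is.null(freqs)) freqs <- seq_len(nf)
  cross_spectra(freqs, out)
}
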