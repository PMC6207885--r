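#' Specification of a synthetic clinical cohort
#'
#' Defines the generative conditions for a three-group cohort emulating the
#' clinical study structure: neurological controls, encephalopathic
#' controls, and NMDAR-antibody encephalitis. Group effects are additive
#' shifts on the 41 log-scale neuronal parameters. The default encephalitis
#' effect is a negative shift on NMDA rate constants at the right parietal
#' and both prefrontal sources and on the intrinsic NMDA-to-excitatory
#' weights at the right parietal and left prefrontal sources; the default
#' encephalopathy effect spreads smaller shifts across all three receptor
#' classes.
#'
#' @param n_control,n_encephalopathy,n_nmdar Group sizes (default 18/18/29).
#' @param effects Named list of per-group effect vectors on log-parameters.
#' @param subject_sd Between-subject SD on every log parameter.
#' @param n_epochs Number of 5-s epochs summarized per subject (sets the
#'   sampling noise of fast-mode cross-spectra).
#' @param duration,rate Recording length (s) and sampling rate (Hz) for
#'   time-series mode.
#' @param sensor_noise_sd Additive white sensor noise, uV.
#' @param channel_gain Scaling from source units to scalp uV.
#' @param alpha_amplitude Occipital 10 Hz confound amplitude, uV (0 = off).
#' @param alpha_fraction Fraction of encephalitis subjects receiving the
#'   alpha confound.
#' @param alpha_base Baseline occipital alpha amplitude present in every
#'   subject (uV; log-normal between-subject variability, SD 0.3 on the log
#'   scale). Gives the alpha-power covariate within-group variance, as in
#'   real resting EEG.
#' @param bands Named list of fitted frequency bands, Hz.
#' @param master_seed Seed from which all per-subject seeds derive.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 18, n_encephalopathy = 18,
                        n_nmdar = 29,
                        effects = default_group_effects(),
                        subject_sd = 0.1,
                        n_epochs = 144,
                        duration = 720, rate = 250,
                        sensor_noise_sd = 2,
                        channel_gain = 25,
                        alpha_amplitude = 0,
                        alpha_fraction = 0.2,
                        alpha_base = 0,
                        bands = list(delta = c(2, 6), beta = c(20, 48)),
                        master_seed = 1) {
  stopifnot(n_control >= 1, n_encephalopathy >= 1, n_nmdar >= 1,
            subject_sd >= 0, alpha_fraction >= 0, alpha_fraction <= 1)
  structure(list(n = c(control = n_control,
                       encephalopathy = n_encephalopathy,
                       nmdar = n_nmdar),
                 effects = effects, subject_sd = subject_sd,
                 n_epochs = n_epochs, duration = duration, rate = rate,
                 sensor_noise_sd = sensor_noise_sd,
                 channel_gain = channel_gain,
                 alpha_amplitude = alpha_amplitude,
                 alpha_fraction = alpha_fraction,
                 alpha_base = alpha_base,
                 bands = bands, master_seed = master_seed),
            class = "cohort_spec")
}

#' Default group effect vectors
#'
#' @param encephalitis_shift Log-scale deficit applied to the NMDA rate
#'   constants (right parietal, both prefrontal) and NMDA-to-excitatory
#'   weights (right parietal, left prefrontal).
#' @param net Network whose source names the labels use.
#' @return Named list with `nmdar` and `encephalopathy` effect vectors.
#' @export
default_group_effects <- function(encephalitis_shift = -0.5,
                                  net = build_default_network()) {
  src <- net$sources
  nm <- c(setNames(rep(encephalitis_shift, 3),
                   paste0("kappa_NMDA.",
                          c("parietal.R", "frontal.R", "frontal.L"))),
          setNames(rep(encephalitis_shift, 2),
                   paste0("w_NMDA_E.", c("parietal.R", "frontal.L"))))
  oth <- c(setNames(rep(-0.2, length(src)), paste0("kappa_AMPA.", src)),
           setNames(rep(-0.2, length(src)), paste0("kappa_GABAA.", src)),
           setNames(rep(-0.15, length(src)), paste0("kappa_NMDA.", src)),
           setNames(rep(-0.15, length(src)), paste0("w_GABAA.", src)))
  list(nmdar = nm, encephalopathy = oth)
}

#' Sample one subject's ground-truth parameters
#'
#' Group effect plus independent Gaussian between-subject variability on
#' every neuronal log parameter; observation-noise parameters receive the
#' same variability without group effects.
#'
#' @param spec A `cohort_spec`.
#' @param group One of `"control"`, `"encephalopathy"`, `"nmdar"`.
#' @param net The network defining parameter labels.
#' @return Named parameter vector (neuronal + noise labels).
#' @export
sample_subject_params <- function(spec, group,
                                  net = build_default_network()) {
  labs <- param_labels(net)
  lam <- setNames(rnorm(length(labs), 0, spec$subject_sd), labs)
  eff <- spec$effects[[group]]
  if (!is.null(eff)) {
    if (!all(names(eff) %in% labs))
      stop("effect vector uses unknown labels")
    lam[names(eff)] <- lam[names(eff)] + eff
  }
  nz <- setNames(rnorm(3, 0, spec$subject_sd), noise_labels())
  c(lam, nz)
}

# occipital alpha confound: Cauchy-shaped 10 Hz power spectral density
alpha_psd <- function(freqs, amplitude, f0 = 10, hwhm = 0.8) {
  amplitude^2 * (hwhm / pi) / ((freqs - f0)^2 + hwhm^2)
}

# channel-level model CSD for a subject: gain^2 * Lpop S Lpop' + sensor
# noise floor (+ alpha component on O1/O2 when amp > 0)
channel_csd <- function(lambda, net, lf, freqs, spec, constants) {
  rp <- resolve_params(lambda, net, constants)
  nsrc <- length(net$sources)
  n <- 16L * nsrc
  pw <- lf$pop_weights[constants$populations]
  Lpop <- matrix(0, nrow(lf$gain), n)
  for (s in seq_len(nsrc))
    for (p in 1:4)
      Lpop[, state_index(s, p, 1L)] <- lf$gain[, s] * pw[p]
  B <- matrix(0, n, nsrc)
  for (s in seq_len(nsrc)) B[state_index(s, 1L, 1L), s] <- 1 / constants$C
  gu <- innovations_psd(rp$noise, freqs)
  pr <- .cmc_predict(rp$ctx, freqs, Lpop * spec$channel_gain, B, gu,
                     default_x0(rp$ctx), 1e-8, 100, TRUE, 4000L)
  if (pr$status == "unstable") stop_unstable(pr$max_real)
  if (pr$status != "ok") stop("forward prediction failed: ", pr$status)
  S <- pr$csd
  nch <- nrow(lf$gain)
  floor_ <- spec$sensor_noise_sd^2 / spec$rate
  for (k in seq_along(freqs)) S[, , k] <- S[, , k] + diag(floor_, nch)
  S
}

add_alpha_csd <- function(S, freqs, channels, amplitude, rate) {
  o <- match(c("O1", "O2"), channels)
  if (anyNA(o)) return(S)
  pa <- alpha_psd(freqs, amplitude)
  for (k in seq_along(freqs)) {
    S[o, o, k] <- S[o, o, k] + pa[k] * matrix(c(1, 0.8, 0.8, 1), 2)
  }
  S
}

# subject-specific spatial modes from the broadband channel covariance
modes_from_csd <- function(S_broad, k = 8) {
  C <- apply(Re(S_broad), c(1, 2), sum)
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  M <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

# finite-sample cross-spectral estimate: complex-Wishart average of K
# epoch outer products around the model CSD (Hermitian factor via
# eigen-decomposition; base chol() does not support complex matrices)
sample_csd <- function(S, K) {
  nm <- dim(S)[1]; nf <- dim(S)[3]
  out <- array(0i, dim(S))
  for (f in seq_len(nf)) {
    Sf <- (S[, , f] + t(Conj(S[, , f]))) / 2
    eg <- eigen(Sf, symmetric = TRUE)
    d <- pmax(Re(eg$values), 0)
    R <- eg$vectors %*% diag(sqrt(d), nm)
    Z <- (matrix(rnorm(nm * K), nm) + 1i * matrix(rnorm(nm * K), nm)) /
      sqrt(2)
    X <- R %*% Z
    Sh <- X %*% t(Conj(X)) / K
    out[, , f] <- (Sh + t(Conj(Sh))) / 2
  }
  out
}

#' Simulate one subject's sensor time series
#'
#' Euler-Maruyama integration of the full nonlinear (delayed) network
#' driven by white-noise innovations into the spiny stellate populations,
#' projected through the population-weighted lead field, with additive
#' white sensor noise and an optional occipital 10 Hz oscillation on
#' O1/O2.
#'
#' @param lambda Named parameter vector (see [sample_subject_params()]).
#' @param spec A `cohort_spec`.
#' @param lf A `lead_field`.
#' @param net The source network.
#' @param alpha Add the occipital alpha confound?
#' @param dt Integration step, ms.
#' @param constants Constant set.
#' @return An `eeg_recording` at `spec$rate`.
#' @export
simulate_sensor_timeseries <- function(lambda, spec, lf,
                                       net = build_default_network(),
                                       alpha = FALSE, dt = 0.5,
                                       constants = cmc_constants()) {
  rp <- resolve_params(lambda, net, constants)
  lin <- linearize(lambda, net, constants = constants)
  if (lin$max_real >= 0) stop_unstable(lin$max_real)
  decim <- round(1000 / (dt * spec$rate))
  if (abs(decim * dt * spec$rate - 1000) > 1e-6)
    stop("sampling rate must divide the simulation rate")
  nsim <- ceiling(spec$duration * 1000 / dt)
  innov_sd <- rp$noise$u_amp * sqrt(1000)
  V <- .cmc_simulate(rp$ctx, lin$x, dt, nsim, 1L, innov_sd,
                     burn_steps = round(2000 / dt))
  nsrc <- length(net$sources)
  pw <- lf$pop_weights[constants$populations]
  W <- matrix(0, nsrc * 4, nsrc)
  for (s in seq_len(nsrc)) W[(s - 1) * 4 + (1:4), s] <- pw
  src_sig <- t(W) %*% (V - rowMeans(V))
  ch <- spec$channel_gain * lf$gain %*% src_sig
  # decimate to the recording rate with an anti-aliasing FIR
  ch_dec <- t(apply(ch, 1, function(x)
    signal::decimate(x, decim, ftype = "fir")))
  n <- ncol(ch_dec)
  ch_dec <- ch_dec + matrix(rnorm(length(ch_dec), 0, spec$sensor_noise_sd),
                            nrow(ch_dec))
  if (alpha && spec$alpha_amplitude > 0) {
    tt <- seq_len(n) / spec$rate
    z <- complex(real = rnorm(1), imaginary = rnorm(1)) / sqrt(2)
    rot <- exp(complex(imaginary = 2 * pi * 10 / spec$rate) -
                 0.8 * pi / spec$rate)
    zs <- complex(real = numeric(n))
    innov <- (rnorm(n) + 1i * rnorm(n)) / sqrt(2)
    drive <- sqrt(1 - Mod(rot)^2)
    for (i in seq_len(n)) {
      z <- z * rot + drive * innov[i]
      zs[i] <- z
    }
    a_sig <- sqrt(2) * spec$alpha_amplitude * Re(zs)
    o <- match(c("O1", "O2"), lf$channels)
    if (!anyNA(o)) {
      ch_dec[o[1], ] <- ch_dec[o[1], ] + a_sig
      ch_dec[o[2], ] <- ch_dec[o[2], ] + 0.8 * a_sig
    }
  }
  recording(ch_dec, spec$rate, lf$channels)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject ground-truth parameters, then either synthesizes
#' finite-sample sensor-mode cross-spectra analytically (`mode = "csd"`,
#' the fast path: model channel CSD + complex-Wishart epoch noise,
#' subject-specific spatial modes) or simulates full sensor time series
#' (`mode = "timeseries"`). Unstable parameter draws are rejected and
#' resampled (logged in the output). Everything derives from
#' `spec$master_seed`.
#'
#' @param spec A `cohort_spec`.
#' @param mode `"csd"` or `"timeseries"`.
#' @param net,lf Network and lead field (defaults built internally).
#' @param out_dir Optional directory: writes `groups.csv`,
#'   `ground_truth.csv` and, in time-series mode, per-subject EDF files.
#' @param constants Constant set.
#' @param max_resample Resampling attempts per subject for unstable draws.
#' @return Object of class `cohort`: `table` (id, group, seed, alpha flag,
#'   alpha power), `lambda` (subjects x parameters ground truth), `csd`
#'   (per band, per subject), `modes` (per subject), `recordings` (paths or
#'   objects in time-series mode), `lf`, `net`, `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), mode = c("csd",
                                                           "timeseries"),
                            net = build_default_network(),
                            lf = NULL, out_dir = NULL,
                            constants = cmc_constants(),
                            max_resample = 10) {
  mode <- match.arg(mode)
  if (is.null(lf)) lf <- make_lead_field(net)
  groups <- rep(names(spec$n), spec$n)
  ns <- length(groups)
  set.seed(spec$master_seed)
  seeds <- sample.int(.Machine$integer.max / 2, ns)
  n_alpha <- round(spec$alpha_fraction * spec$n[["nmdar"]])
  alpha_ids <- if (spec$alpha_amplitude > 0 && n_alpha > 0)
    sample(which(groups == "nmdar"), n_alpha) else integer(0)
  labs <- c(param_labels(net), noise_labels())
  lambda <- matrix(NA_real_, ns, length(labs),
                   dimnames = list(NULL, labs))
  csd <- lapply(spec$bands, function(b) vector("list", ns))
  modes <- vector("list", ns)
  recordings <- vector("list", ns)
  alpha_power <- numeric(ns)
  resampled <- integer(0)
  broad_grid <- seq(2, 48, by = 2)
  for (i in seq_len(ns)) {
    set.seed(seeds[i])
    lam <- NULL
    for (try_ in seq_len(max_resample)) {
      cand <- sample_subject_params(spec, groups[i], net)
      st <- tryCatch(linearize(cand[param_labels(net)], net,
                               constants = constants)$max_real,
                     error = function(e) Inf)
      if (st < 0) { lam <- cand; break }
      resampled <- c(resampled, i)
    }
    if (is.null(lam))
      stop("subject ", i, " unstable after ", max_resample, " resamples")
    lambda[i, ] <- lam
    with_alpha <- i %in% alpha_ids
    a_amp <- if (spec$alpha_base > 0)
      spec$alpha_base * exp(rnorm(1, 0, 0.3)) else 0
    if (with_alpha) a_amp <- sqrt(a_amp^2 + spec$alpha_amplitude^2)
    if (mode == "csd") {
      Sb <- channel_csd(lam, net, lf, broad_grid, spec, constants)
      if (a_amp > 0)
        Sb <- add_alpha_csd(Sb, broad_grid, lf$channels, a_amp, spec$rate)
      o <- match(c("O1", "O2"), lf$channels)
      asel <- broad_grid >= 8 & broad_grid <= 12
      alpha_power[i] <- mean(Re(Sb[o[1], o[1], asel] + Sb[o[2], o[2],
                                                          asel])) / 2
      M <- modes_from_csd(Sb)
      rownames(M) <- lf$channels
      modes[[i]] <- M
      for (b in names(spec$bands)) {
        fr <- seq(spec$bands[[b]][1], spec$bands[[b]][2], by = 1)
        Sc <- channel_csd(lam, net, lf, fr, spec, constants)
        if (a_amp > 0)
          Sc <- add_alpha_csd(Sc, fr, lf$channels, a_amp, spec$rate)
        Sm <- array(0i, c(ncol(M), ncol(M), length(fr)))
        for (k in seq_along(fr))
          Sm[, , k] <- t(M) %*% Sc[, , k] %*% M
        Sm <- sample_csd(Sm, spec$n_epochs)
        csd[[b]][[i]] <- cross_spectra(fr, Sm, tol = 1e-6)
      }
    } else {
      rec <- simulate_sensor_timeseries(lam, spec, lf, net,
                                        alpha = with_alpha,
                                        constants = constants)
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        path <- file.path(out_dir, sprintf("subject_%02d.edf", i))
        write_edf(rec, path)
        recordings[[i]] <- path
      } else recordings[[i]] <- rec
    }
  }
  tab <- data.frame(id = sprintf("s%02d", seq_len(ns)), group = groups,
                    seed = seeds,
                    alpha_confound = seq_len(ns) %in% alpha_ids,
                    alpha_power = alpha_power,
                    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(tab, file.path(out_dir, "groups.csv"), row.names = FALSE)
    write.csv(cbind(tab["id"], as.data.frame(lambda)),
              file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  }
  structure(list(table = tab, lambda = lambda, csd = csd, modes = modes,
                 recordings = recordings, lf = lf, net = net, spec = spec,
                 resampled = resampled),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$table), "subjects (",
      paste(names(table(x$table$group)), table(x$table$group),
            sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Invert every subject of a synthetic cohort
#'
#' Runs the subject-level variational Laplace inversions for one band,
#' optionally after the empirical-prior calibration step (three randomly
#' chosen neurological controls are inverted under the default priors and
#' their average posterior mean becomes the prior mean for every subject).
#'
#' @param cohort A `cohort` generated in `"csd"` mode.
#' @param band Name of the band in `cohort$spec$bands`.
#' @param priors Prior density (default [default_priors()]).
#' @param control Settings from [vl_control()].
#' @param empirical_calibration Apply the three-control calibration step?
#' @param calibration_seed Seed for the random choice of controls.
#' @return List of `cmc_posterior`, one per subject, with the calibrated
#'   priors attached as an attribute.
#' @export
invert_cohort <- function(cohort, band = "beta",
                          priors = default_priors(cohort$net),
                          control = vl_control(),
                          empirical_calibration = TRUE,
                          calibration_seed = 1) {
  if (!band %in% names(cohort$spec$bands)) stop("unknown band: ", band)
  fr <- seq(cohort$spec$bands[[band]][1], cohort$spec$bands[[band]][2],
            by = 1)
  ns <- nrow(cohort$table)
  fwd_for <- function(i)
    forward_model(cohort$net, cohort$lf, cohort$modes[[i]], fr)
  pr <- priors
  if (empirical_calibration) {
    ctrl <- which(cohort$table$group == "control")
    set.seed(calibration_seed)
    ref <- sample(ctrl, min(3L, length(ctrl)))
    ref_post <- lapply(ref, function(i)
      variational_laplace(cohort$csd[[band]][[i]], fwd_for(i), priors,
                          control))
    pr <- calibrate_empirical_priors(ref_post, priors)
  }
  out <- vector("list", ns)
  for (i in seq_len(ns)) {
    out[[i]] <- variational_laplace(cohort$csd[[band]][[i]], fwd_for(i),
                                    pr, control)
  }
  names(out) <- cohort$table$id
  attr(out, "priors") <- pr
  out
}
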