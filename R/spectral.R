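#' Multichannel EEG recording container
#'
#' @param samples Channel x sample matrix, microvolts.
#' @param rate Sampling rate, Hz (250-500 for clinical recordings).
#' @param channels Channel labels; defaults to the 21-channel 10-20 montage
#'   when the channel count matches.
#' @return Object of class `eeg_recording`.
#' @export
recording <- function(samples, rate, channels = NULL) {
  samples <- as.matrix(samples)
  if (is.null(channels))
    channels <- if (nrow(samples) == 21L) montage_1020()
                else paste0("ch", seq_len(nrow(samples)))
  if (length(channels) != nrow(samples))
    stop("channel labels do not match the number of rows")
  structure(list(samples = samples, rate = rate, channels = channels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("eeg_recording:", nrow(x$samples), "channels x",
      ncol(x$samples), "samples @", x$rate, "Hz (",
      round(ncol(x$samples) / x$rate, 1), "s )\n")
  invisible(x)
}

#' Epoch, artifact-reject and low-pass filter a recording
#'
#' Splits the recording into fixed-length epochs, demeans each channel per
#' epoch, rejects epochs in which any channel exceeds the absolute-amplitude
#' or sample-to-sample gradient threshold (an automated surrogate for visual
#' artifact inspection), and low-pass filters the survivors with a
#' zero-phase 4th-order Butterworth filter.
#'
#' @param rec An `eeg_recording`.
#' @param amplitude_threshold Reject epochs with |amplitude| above this, uV.
#' @param gradient_threshold Reject epochs with successive-sample jumps
#'   above this, uV.
#' @param epoch_length Epoch length, s.
#' @param lowpass Low-pass corner frequency, Hz.
#' @return Object of class `epoch_set`: `epochs` (n_epochs x n_channels x
#'   n_samples), `rate`, `channels`, `epoch_length` and a `rejected` count.
#' @export
preprocess <- function(rec, amplitude_threshold = 100,
                       gradient_threshold = 50, epoch_length = 5,
                       lowpass = 42) {
  n_per <- round(rec$rate * epoch_length)
  n_ep <- floor(ncol(rec$samples) / n_per)
  if (n_ep < 1L) stop("recording shorter than one epoch")
  bf <- signal::butter(4, lowpass / (rec$rate / 2), type = "low")
  keep <- list()
  rejected <- 0L
  for (e in seq_len(n_ep)) {
    idx <- ((e - 1L) * n_per + 1L):(e * n_per)
    seg <- rec$samples[, idx, drop = FALSE]
    seg <- seg - rowMeans(seg)
    if (max(abs(seg)) > amplitude_threshold ||
        max(abs(t(apply(seg, 1, diff)))) > gradient_threshold) {
      rejected <- rejected + 1L
      next
    }
    filt <- t(apply(seg, 1, function(ch) signal::filtfilt(bf, ch)))
    keep[[length(keep) + 1L]] <- filt
  }
  if (!length(keep))
    stop("no epochs survived artifact rejection (", rejected, " rejected)")
  ep <- array(0, c(length(keep), nrow(rec$samples), n_per))
  for (e in seq_along(keep)) ep[e, , ] <- keep[[e]]
  structure(list(epochs = ep, rate = rec$rate, channels = rec$channels,
                 epoch_length = epoch_length, rejected = rejected),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("epoch_set:", dim(x$epochs)[1], "epochs x", dim(x$epochs)[2],
      "channels x", dim(x$epochs)[3], "samples (", x$rejected,
      "rejected )\n")
  invisible(x)
}

#' Spatial principal modes of an epoch set
#'
#' Singular value decomposition of the concatenated channel x time data
#' matrix; the top `k` left singular vectors summarize the spatial
#' distribution of scalp responses and compress the data for model fitting.
#' Each mode's largest-magnitude element is forced positive to fix the SVD
#' sign ambiguity.
#'
#' @param es An `epoch_set`.
#' @param k Number of modes to retain (default 8).
#' @return Object of class `spatial_modes`: `M` (channels x k, orthonormal
#'   columns) and `singular_values`.
#' @export
compute_spatial_modes <- function(es, k = 8) {
  nch <- dim(es$epochs)[2]
  if (k > nch) stop("k exceeds the channel count")
  X <- matrix(aperm(es$epochs, c(2, 3, 1)), nrow = nch)
  X <- X - rowMeans(X)
  sv <- svd(X, nu = k, nv = 0)
  M <- sv$u
  for (j in seq_len(k)) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  rownames(M) <- es$channels
  structure(list(M = M, singular_values = sv$d, k = k),
            class = "spatial_modes")
}

#' Autoregressive sensor-mode cross-spectral density
#'
#' Projects each epoch onto the spatial modes, fits a multivariate
#' (vector) autoregressive model per epoch by Yule-Walker, evaluates its
#' parametric cross-spectrum `S(f) = A(f)^-1 Sigma A(f)^-H / fs` on the
#' requested grid, and averages the per-epoch spectra (robust to epoch-wise
#' non-stationarity).
#'
#' @param es An `epoch_set`.
#' @param modes A `spatial_modes` (or channel x k matrix).
#' @param order Autoregressive model order (default 8).
#' @param band Frequency band `c(f_lo, f_hi)`, Hz.
#' @param df Frequency resolution, Hz.
#' @return A `cross_spectra` over `seq(band[1], band[2], by = df)`.
#' @export
mar_cross_spectra <- function(es, modes, order = 8, band = c(20, 48),
                              df = 1) {
  M <- if (inherits(modes, "spatial_modes")) modes$M else modes
  if (order < 1L) stop("AR order must be >= 1")
  if (band[1] <= 0 || band[2] >= es$rate / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  freqs <- seq(band[1], band[2], by = df)
  k <- ncol(M)
  nep <- dim(es$epochs)[1]
  acc <- array(0i, c(k, k, length(freqs)))
  used <- 0L
  for (e in seq_len(nep)) {
    Y <- t(M) %*% es$epochs[e, , ]       # k x time
    fit <- tryCatch(
      ar(t(Y), aic = FALSE, order.max = order, method = "yule-walker",
         demean = TRUE),
      error = function(err)
        stop("autoregressive fit failed on epoch ", e, " (",
             conditionMessage(err), "); data may be rank-deficient"))
    acc <- acc + ar_spectrum(fit, freqs, es$rate, k)
    used <- used + 1L
  }
  S <- acc / used
  for (i in seq_along(freqs)) S[, , i] <- (S[, , i] + t(Conj(S[, , i]))) / 2
  cross_spectra(freqs, S, tol = 1e-6)
}

# parametric spectrum of a fitted (possibly multivariate) AR model;
# two-sided density per Hz
ar_spectrum <- function(fit, freqs, fs, k) {
  ord <- fit$order
  A <- fit$ar
  if (k == 1L) A <- array(A, c(max(ord, length(A)), 1L, 1L))
  Sig <- fit$var.pred
  if (length(Sig) == 1L) Sig <- matrix(Sig, 1, 1)
  out <- array(0i, c(k, k, length(freqs)))
  for (i in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[i] / fs)
    Af <- diag(1 + 0i, k)
    if (ord >= 1L)
      for (m in seq_len(ord)) Af <- Af - A[m, , ] * z^m
    H <- solve(Af)
    out[, , i] <- H %*% Sig %*% t(Conj(H)) / fs
  }
  out
}

#' Band-averaged autospectral power of one mode
#'
#' @param cs A `cross_spectra`.
#' @param band `c(f_lo, f_hi)`, Hz; must lie within the frequency grid.
#' @param mode_index Which mode's autospectrum to summarize (default 1).
#' @return Mean absolute autospectral power over the band.
#' @export
band_power_summary <- function(cs, band, mode_index = 1) {
  if (mode_index < 1 || mode_index > dim(cs$S)[1])
    stop("mode index out of range")
  sel <- cs$freqs >= band[1] & cs$freqs <= band[2]
  if (!any(sel)) stop("band outside the frequency grid")
  mean(Mod(cs$S[mode_index, mode_index, sel]))
}

#' Group comparison of band-power summaries
#'
#' One-way analysis of variance across groups, followed by post hoc pairwise
#' Welch t-tests with Bonferroni correction.
#'
#' @param summaries Per-subject scalar summaries.
#' @param groups Per-subject group labels (factor or character).
#' @return List with `F`, `p`, `df`, and a `pairwise` data frame of
#'   corrected p-values.
#' @export
group_band_anova <- function(summaries, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("need at least two groups with at least two subjects each")
  if (stats::var(summaries) == 0) {
    pairs <- utils::combn(levels(groups), 2)
    return(list(F = 0, p = 1,
                df = c(nlevels(groups) - 1L,
                       length(summaries) - nlevels(groups)),
                pairwise = data.frame(group1 = pairs[1, ],
                                      group2 = pairs[2, ],
                                      p_raw = 1, p_corrected = 1)))
  }
  a <- anova(lm(summaries ~ groups))
  pairs <- utils::combn(levels(groups), 2)
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_raw = apply(pairs, 2, function(pr)
      tryCatch(t.test(summaries[groups == pr[1]],
                      summaries[groups == pr[2]])$p.value,
               error = function(e) NA_real_)))
  pw$p_corrected <- pmin(1, pw$p_raw * ncol(pairs))  # Bonferroni
  list(F = a[["F value"]][1], p = a[["Pr(>F)"]][1],
       df = c(a$Df[1], a$Df[2]), pairwise = pw)
}

#' Welch cross-spectral density estimate
#'
#' Hann-windowed, overlapping-segment estimate of the full complex
#' cross-spectral matrix of a multichannel series (two-sided density per
#' Hz), used as the nonparametric counterpart of [mar_cross_spectra()].
#'
#' @param x Channel x sample matrix.
#' @param rate Sampling rate, Hz.
#' @param nseg Segment length in samples (default 2 s worth).
#' @param overlap Fractional overlap between segments.
#' @return A `cross_spectra` on the grid `(0:(nseg/2)) * rate / nseg`.
#' @export
welch_csd <- function(x, rate, nseg = round(2 * rate), overlap = 0.5) {
  x <- as.matrix(x)
  nch <- nrow(x); n <- ncol(x)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  norm <- rate * sum(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- array(0i, c(nch, nch, nf))
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    X <- t(apply(sweep(seg, 2, w, "*"), 1, fft))[, seq_len(nf), drop = FALSE]
    for (i in seq_len(nf))
      acc[, , i] <- acc[, , i] + X[, i] %*% t(Conj(X[, i, drop = FALSE]))
  }
  S <- acc / (length(starts) * norm)
  freqs <- (seq_len(nf) - 1L) * rate / nseg
  for (i in seq_len(nf)) S[, , i] <- (S[, , i] + t(Conj(S[, , i]))) / 2
  cross_spectra(freqs, S, tol = 1e-6)
}
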