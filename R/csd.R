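#' Cross-spectral density container
#'
#' Complex Hermitian cross-spectral density over a frequency grid: an
#' `n x n x n_freq` array whose slices are Hermitian with real, non-negative
#' diagonals.
#'
#' @param freqs Frequency grid, Hz.
#' @param S Complex array `n x n x n_freq`.
#' @param tol Hermitian-symmetry tolerance relative to the slice norm.
#' @return Object of class `cross_spectra`.
#' @export
cross_spectra <- function(freqs, S, tol = 1e-8) {
  if (length(dim(S)) != 3L || dim(S)[1] != dim(S)[2])
    stop("S must be an n x n x n_freq array")
  if (dim(S)[3] != length(freqs))
    stop("third dimension of S must match the frequency grid")
  for (i in seq_len(dim(S)[3])) {
    d <- max(Mod(S[, , i] - t(Conj(S[, , i]))))
    if (d > tol * max(1, max(Mod(S[, , i]))))
      stop("cross-spectral slice ", i, " is not Hermitian (deviation ", d, ")")
  }
  structure(list(freqs = as.numeric(freqs), S = S), class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat("cross_spectra:", dim(x$S)[1], "x", dim(x$S)[2], "over",
      length(x$freqs), "frequencies [", min(x$freqs), "-", max(x$freqs),
      "Hz ]\n")
  invisible(x)
}

#' @export
dim.cross_spectra <- function(x) dim(x$S)

#' Write / read cross-spectra in the package's array container
#'
#' JSON layout mirrors an HDF5-style hierarchy: `csd/freqs`, `csd/real`,
#' `csd/imag` (row-major nested arrays), and optionally `modes` for a spatial
#' mode matrix.
#'
#' @param cs A `cross_spectra`.
#' @param path Output path (`.json`).
#' @param modes Optional spatial-mode matrix stored alongside.
#' @return `write_csd` returns `path` invisibly; `read_csd` a list with
#'   elements `csd` (a `cross_spectra`) and `modes` (or `NULL`).
#' @export
write_csd <- function(cs, path, modes = NULL) {
  payload <- list(csd = list(freqs = cs$freqs,
                             dim = dim(cs$S),
                             real = as.numeric(Re(cs$S)),
                             imag = as.numeric(Im(cs$S))))
  if (!is.null(modes))
    payload$modes <- list(dim = dim(modes), data = as.numeric(modes))
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' @rdname write_csd
#' @export
read_csd <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  dm <- as.integer(d$csd$dim)
  S <- array(complex(real = d$csd$real, imaginary = d$csd$imag), dm)
  modes <- if (!is.null(d$modes))
    array(as.numeric(d$modes$data), as.integer(d$modes$dim)) else NULL
  list(csd = cross_spectra(as.numeric(d$csd$freqs), S), modes = modes)
}

# internal: per-entry weights 1/sqrt(S_ii S_jj) on the data-vector layout,
# computed from a reference (observed) cross-spectral density
csd_weights <- function(cs, floor_frac = 1e-6) {
  n <- dim(cs$S)[1]
  up <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  ups <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  as.numeric(vapply(seq_along(cs$freqs), function(k) {
    d <- pmax(Re(diag(cs$S[, , k])), 0)
    d <- pmax(d, floor_frac * max(d))
    c(1 / sqrt(d[up[, 1]] * d[up[, 2]]),
      1 / sqrt(d[ups[, 1]] * d[ups[, 2]]))
  }, numeric(nrow(up) + nrow(ups))))
}

# internal: vectorize a Hermitian CSD into its non-redundant real data
# vector: per frequency, real parts of upper triangle incl. diagonal then
# imaginary parts of the strict upper triangle.
csd_to_datavec <- function(cs) {
  n <- dim(cs$S)[1]
  up <- upper.tri(matrix(0, n, n), diag = TRUE)
  ups <- upper.tri(matrix(0, n, n))
  as.numeric(vapply(seq_along(cs$freqs), function(i) {
    s <- cs$S[, , i]
    c(Re(s[up]), Im(s[ups]))
  }, numeric(sum(up) + sum(ups))))
}

#' Number of spectral data features in a band
#'
#' The fitted data form an `n_modes x n_modes` matrix per frequency; with a
#' 1 Hz grid and inclusive endpoints the 20-48 Hz band yields
#' `8^2 x 29 = 1856` real and as many complex (imaginary-part) tallies, and
#' the 2-6 Hz band yields 320 of each.
#'
#' @param band Numeric `c(f_lo, f_hi)`, Hz.
#' @param df Frequency resolution, Hz (must divide the band width).
#' @param n_modes Number of spatial modes.
#' @return Integer count `n_modes^2 * n_frequencies`.
#' @export
count_data_points <- function(band, df = 1, n_modes = 8) {
  if (length(band) != 2L || band[2] < band[1]) stop("empty band")
  w <- band[2] - band[1]
  if (abs(w / df - round(w / df)) > 1e-9)
    stop("`df` must divide the band width")
  nf <- as.integer(round(w / df)) + 1L
  as.integer(n_modes^2 * nf)
}
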