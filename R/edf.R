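#' Read and write European Data Format (EDF) recordings
#'
#' Minimal EDF support for round-tripping continuous multichannel
#' recordings: a single fixed sampling rate across channels, 16-bit samples,
#' 1-second data records. Physical scaling is chosen per channel from the
#' data range, so amplitudes survive the round trip to within the 16-bit
#' quantization step.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file.
#' @param patient,recording_id Free-text EDF header fields.
#' @return `write_edf` returns `path` invisibly; `read_edf` an
#'   `eeg_recording`.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "cmcEEG") {
  ns <- nrow(rec$samples)
  spr <- as.integer(round(rec$rate))     # samples per 1 s record
  nrec <- floor(ncol(rec$samples) / spr)
  if (nrec < 1L) stop("recording shorter than one EDF data record")
  x <- rec$samples[, seq_len(nrec * spr), drop = FALSE]
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  too_flat <- (pmax_ - pmin_) < 1e-6
  pmin_[too_flat] <- pmin_[too_flat] - 1; pmax_[too_flat] <- pmax_[too_flat] + 1
  dmin <- -32768L; dmax <- 32767L
  pad <- function(s, n) {
    s <- substr(as.character(s), 1, n)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad(patient, 80), pad(recording_id, 80),
                   pad("01.01.26", 8), pad("00.00.00", 8),
                   pad(256 * (ns + 1), 8), pad("", 44), pad(nrec, 8),
                   pad("1", 8), pad(ns, 4)),
            con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad, "", n = width), collapse = ""),
              con, eos = NULL)
  field(rec$channels, 16)
  field(rep("AgAgCl electrode", ns), 80)
  field(rep("uV", ns), 8)
  field(sprintf("%.8g", pmin_), 8)
  field(sprintf("%.8g", pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((x[ch, idx] - pmin_[ch]) / gain[ch]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  ns <- as.integer(substr(hdr, 253, 256))
  nrec <- as.integer(substr(hdr, 237, 244))
  dur <- as.numeric(substr(hdr, 245, 252))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  fld <- function(offset, width) {
    out <- character(ns)
    for (i in seq_len(ns))
      out[i] <- trimws(substr(sig, offset + (i - 1) * width + 1,
                              offset + i * width))
    out
  }
  labels <- fld(0, 16)
  pmin_ <- as.numeric(fld(ns * (16 + 80 + 8), 8))
  pmax_ <- as.numeric(fld(ns * (16 + 80 + 8 + 8), 8))
  dmin <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8), 8))
  dmax <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(fld(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  out <- matrix(0, ns, nrec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      out[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  recording(out, spr[1] / dur, labels)
}
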