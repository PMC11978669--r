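#' Read and write EDF recordings
#'
#' A minimal reader/writer for the European Data Format (EDF), sufficient to
#' round-trip the recordings this package produces: identical sampling rate on
#' every channel, 16-bit samples, one-second data records. Physical scaling is
#' preserved to the resolution of the 16-bit quantisation.
#'
#' @param rec An [ieeg_recording()].
#' @param path File path ending in `.edf`.
#' @return `write_edf()` returns `path` invisibly; `read_edf()` returns an
#'   [ieeg_recording()].
#' @examples
#' rec <- ieeg_recording(matrix(sin(seq_len(512) / 10), nrow = 1), fs_hz = 256)
#' f <- tempfile(fileext = ".edf")
#' write_edf(rec, f)
#' rt <- read_edf(f)
#' max(abs(rt$samples - rec$samples)) < 1e-3
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ieeg_recording"))
  fs <- rec$fs_hz
  if (fs != round(fs)) {
    abort("EDF export requires an integer sampling rate.", class = "hfo_config_error")
  }
  x <- rec$samples
  ns <- nrow(x)
  spr <- as.integer(fs)                      # samples per 1 s record, per channel
  n_rec <- floor(ncol(x) / spr)
  if (n_rec < 1) abort("Recording shorter than one EDF data record (1 s).")
  x <- x[, seq_len(n_rec * spr), drop = FALSE]

  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(s, w) {
    s <- substr(as.character(s), 1, w)
    formatC(s, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),                                   # version
    pad("X X X X", 80),                            # patient id (anonymous)
    pad("Startdate X X X X", 80),                  # recording id
    pad("01.01.00", 8), pad("00.00.00", 8),        # date, time
    pad(256 + 256 * ns, 8),                        # header bytes
    pad("", 44),                                   # reserved
    pad(n_rec, 8), pad("1", 8), pad(ns, 4)         # records, duration, ns
  )
  writeChar(hdr, con, nchars = 256, eos = NULL)
  shdr <- paste0(
    paste(vapply(rec$channel_labels, pad, "", w = 16), collapse = ""),
    paste(rep(pad("iEEG", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.8g", pmin), pad, "", w = 8), collapse = ""),
    paste(vapply(sprintf("%.8g", pmax), pad, "", w = 8), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(spr, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(shdr, con, nchars = 256 * ns, eos = NULL)

  gain <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((x[, idx, drop = FALSE] - pmin) * gain + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    # records store channels sequentially: all ch1 samples, then ch2, ...
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(n) as.numeric(trimws(rd(n)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  num(8)                      # header length (implied by ns)
  rd(44)
  n_rec <- num(8); rec_dur <- num(8); ns <- as.integer(num(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  pmin <- vapply(seq_len(ns), function(i) num(8), 0)
  pmax <- vapply(seq_len(ns), function(i) num(8), 0)
  dmin <- vapply(seq_len(ns), function(i) num(8), 0)
  dmax <- vapply(seq_len(ns), function(i) num(8), 0)
  rd(80 * ns)
  spr <- vapply(seq_len(ns), function(i) as.integer(num(8)), 0L)
  rd(32 * ns)
  if (length(unique(spr)) != 1L) {
    abort("Mixed per-channel sampling rates are not supported.")
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    dig <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   signed = TRUE, endian = "little")
    dig <- matrix(dig, nrow = spr[1], ncol = ns)   # channel-sequential layout
    out[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(dig) * gain + (pmin - dmin * gain)
  }
  ieeg_recording(out, fs_hz = fs, channel_labels = labels)
}
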