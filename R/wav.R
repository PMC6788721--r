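# Minimal mono WAV I/O (PCM 16-bit and IEEE float 32-bit). Kept deliberately
# small: enough to feed recorded sounds into the cochlear front-end and to
# export synthesized waveforms.

#' Read a mono WAV file
#'
#' Supports PCM 16-bit and IEEE float 32-bit; multichannel files return the
#' first channel.
#'
#' @param path file path.
#' @return numeric waveform in `[-1, 1]` with attribute `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little",
                         signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little",
                           signed = FALSE),
        fs = readBin(con, "integer", 1, 4, endian = "little"))
      readBin(con, "raw", sz - 8)
    } else if (tag == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV file")
  x <- if (fmt$format == 1) {
    readBin(data, "integer", length(data) / 2, 2, endian = "little") / 32768
  } else if (fmt$format == 3) {
    readBin(data, "double", length(data) / 4, 4, endian = "little")
  } else stop("unsupported WAV encoding (need PCM16 or float32)")
  if (fmt$channels > 1)
    x <- x[seq(1, length(x), by = fmt$channels)]
  structure(x, fs = fmt$fs)
}

#' Write a mono WAV file
#'
#' @param x numeric waveform in `[-1, 1]`.
#' @param path output path.
#' @param fs sampling rate, Hz.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @export
write_wav <- function(x, path, fs, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  con <- file(path, "wb")
  on.exit(close(con))
  nb <- bits / 8
  data_sz <- length(x) * nb
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 16) 1L else 3L, 1L), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * nb), con, 4, endian = "little")
  writeBin(c(as.integer(nb), as.integer(bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, 4, endian = "little")
  if (bits == 16) {
    writeBin(as.integer(pmin(pmax(round(x * 32767), -32768), 32767)), con, 2,
             endian = "little")
  } else {
    writeBin(as.numeric(x), con, 4, endian = "little")
  }
  invisible(path)
}
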