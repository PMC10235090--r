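# Minimal reader/writer for uncompressed RIFF/WAVE files (PCM 16/32-bit and
# IEEE float 32-bit), enough to exchange two-channel vibrometer recordings.
# CSV sample tables are the text-format alternative (see read_samples_csv).

#' Read an uncompressed WAV file
#'
#' @param path file path.
#' @return list with `samples` (matrix, one column per channel, values in
#'   `[-1, 1]` for PCM) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt or data chunk")
  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (fmt$audio_format == 1L) {           # integer PCM
    v <- readBin(data_raw, "integer", n * fmt$n_channels, size = bytes,
                 signed = TRUE, endian = "little")
    v <- v / (2^(fmt$bits - 1))
  } else if (fmt$audio_format == 3L) {    # IEEE float
    v <- readBin(data_raw, "double", n * fmt$n_channels, size = bytes,
                 endian = "little")
  } else stop("unsupported WAV encoding: format tag ", fmt$audio_format)
  list(samples = matrix(v, ncol = fmt$n_channels, byrow = TRUE),
       sample_rate = fmt$sample_rate)
}

#' Write an uncompressed WAV file (IEEE float 32-bit)
#'
#' @param samples numeric vector or matrix (one column per channel).
#' @param sample_rate Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  samples <- as.matrix(samples)
  nc <- ncol(samples); ns <- nrow(samples)
  data_size <- ns * nc * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(x, size) writeBin(as.integer(x), con, size = size,
                                      endian = "little")
  writeChar("RIFF", con, eos = NULL); w_int(36L + data_size, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_int(16L, 4)
  w_int(3L, 2); w_int(nc, 2); w_int(sample_rate, 4)
  w_int(sample_rate * nc * 4L, 4); w_int(nc * 4L, 2); w_int(32L, 2)
  writeChar("data", con, eos = NULL); w_int(data_size, 4)
  writeBin(as.numeric(t(samples)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a CSV table of recorded samples
#'
#' Text-format alternative to WAV: a CSV whose columns are channels
#' (header row), one sample per row.
#'
#' @param path file path.
#' @param sample_rate Hz (CSV carries no rate metadata).
#' @return list with `samples` (matrix) and `sample_rate`.
#' @export
read_samples_csv <- function(path, sample_rate) {
  df <- utils::read.csv(path)
  list(samples = as.matrix(df), sample_rate = sample_rate)
}
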