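# Minimal PCM-16 WAV read/write (RIFF little-endian), enough for mono or
# stereo fixtures. Samples are represented in R as doubles in [-1, 1].

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param waveform Numeric vector (mono) or matrix with one column per
#'   channel, values in \[-1, 1\] (clipped otherwise).
#' @param path Output path.
#' @param sample_rate Samples per second.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate) {
  if (is.null(dim(waveform))) waveform <- matrix(waveform, ncol = 1)
  n_chan <- ncol(waveform)
  x <- t(waveform)                       # interleave channels
  pcm <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
  byte_rate <- sample_rate * n_chan * 2L
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_chan, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(n_chan * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return List with `waveform` (matrix, one column per channel, doubles in
#'   \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  sample_rate <- NULL; n_chan <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop("no data chunk found")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV supported")
      n_chan <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM supported")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size / 2, size = 2,
                     endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  w <- matrix(pcm / 32767, ncol = n_chan, byrow = TRUE)
  list(waveform = w, sample_rate = sample_rate)
}
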