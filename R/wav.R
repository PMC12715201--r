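# Minimal RIFF/WAVE PCM16 I/O. Only uncompressed integer PCM is supported;
# the reader walks the chunk list so files with extra chunks (LIST, fact,
# logger metadata) still load.

readWavPcm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      skip <- sz + (sz %% 2L)
      seek(con, skip, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("corrupt WAV: no fmt chunk in ", path)
  if (is.null(data_raw)) stop("corrupt WAV: no data chunk in ", path)
  if (fmt$format != 1L) stop("unsupported WAV encoding (only integer PCM)")
  if (fmt$bits != 16L) stop("unsupported bit depth: ", fmt$bits, " (only 16-bit PCM)")
  samples <- readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                     signed = TRUE, endian = "little")
  list(samples = samples, sample_rate = fmt$sample_rate,
       channels = fmt$channels, bits = fmt$bits)
}

writeWavPcm <- function(path, samples, sample_rate, channels = 1L) {
  samples <- as.integer(round(samples))
  n_bytes <- length(samples) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                       # PCM
  writeBin(as.integer(channels), con, 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(sample_rate * channels * 2L), con, 4L, endian = "little")
  writeBin(as.integer(channels * 2L), con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4L, endian = "little")
  writeBin(samples, con, 2L, endian = "little")
  invisible(path)
}
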