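#' Read a WAV file as a mono recording
#'
#' Reads a RIFF/WAVE file (integer PCM at 8/16/24/32 bits or IEEE float at
#' 32/64 bits) and returns a [song_rec] object. Multi-channel files are
#' averaged down to mono so that downstream timestamps are channel-agnostic.
#' Samples are scaled to the `[-1, 1]` range.
#'
#' @param path Path to a readable `.wav` file.
#' @return A [song_rec] with the file's native sample rate and the file name
#'   (without extension) as `source_id`.
#' @export
load_wav <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file does not exist: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  bad <- function(why) {
    stop("Unreadable WAV file '", path, "': ", why, call. = FALSE)
  }
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) bad("missing RIFF header")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) bad("missing WAVE header")

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) bad("truncated chunk header")
    if (identical(id, "fmt ")) {
      if (size < 16) bad("fmt chunk too small")
      raw_fmt <- readBin(con, "raw", size + size %% 2L)
      if (length(raw_fmt) < 16L) bad("truncated fmt chunk")
      u16 <- function(i) sum(as.integer(raw_fmt[i + 0:1]) * c(1, 256))
      u32 <- function(i) sum(as.numeric(raw_fmt[i + 0:3]) * 256^(0:3))
      fmt <- list(
        audio_format = u16(1L),
        channels     = u16(3L),
        rate         = u32(5L),
        bits         = u16(15L)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) bad("data chunk before fmt chunk")
      samples <- .read_wav_data(con, size, fmt, bad)
      break
    } else {
      seek(con, size + size %% 2L, origin = "current")
    }
  }
  if (is.null(fmt)) bad("no fmt chunk found")
  if (is.null(samples)) bad("no data chunk found")
  if (fmt$channels > 1L) {
    samples <- matrix(samples, nrow = fmt$channels)
    samples <- colMeans(samples)
  }
  if (length(samples) == 0L) bad("empty data chunk")
  song_rec(samples, fmt$rate,
           source_id = sub("\\.[Ww][Aa][Vv]$", "", basename(path)))
}

.read_wav_data <- function(con, size, fmt, bad) {
  bytes_per <- fmt$bits %/% 8L
  n <- size %/% bytes_per
  if (n <= 0L) bad("empty data chunk")
  if (fmt$audio_format == 3L) {         # IEEE float
    if (!fmt$bits %in% c(32L, 64L)) bad("unsupported float bit depth")
    x <- readBin(con, "double", n, size = bytes_per, endian = "little")
    if (length(x) < n) bad("truncated data chunk")
    return(x)
  }
  if (fmt$audio_format != 1L) bad(paste("unsupported audio format", fmt$audio_format))
  if (fmt$bits == 8L) {                 # unsigned
    x <- readBin(con, "integer", n, size = 1, signed = FALSE)
    if (length(x) < n) bad("truncated data chunk")
    return((x - 128) / 128)
  }
  if (fmt$bits == 16L) {
    x <- readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little")
    if (length(x) < n) bad("truncated data chunk")
    return(x / 32768)
  }
  if (fmt$bits == 24L) {
    raw <- readBin(con, "raw", n * 3L)
    if (length(raw) < n * 3L) bad("truncated data chunk")
    b <- matrix(as.numeric(raw), nrow = 3L)
    x <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    x <- ifelse(x >= 2^23, x - 2^24, x)
    return(x / 2^23)
  }
  if (fmt$bits == 32L) {
    x <- readBin(con, "integer", n, size = 4, endian = "little")
    if (length(x) < n) bad("truncated data chunk")
    return(x / 2^31)
  }
  bad("unsupported PCM bit depth")
}

#' Write a mono recording to a 16-bit PCM WAV file
#'
#' @param rec A [song_rec] (or bare numeric vector with `rate` given).
#' @param path Output path.
#' @param rate Sample rate; taken from `rec` when it is a `song_rec`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, rate = NULL) {
  if (inherits(rec, "song_rec")) {
    samples <- rec$samples
    rate <- rec$rate
  } else {
    samples <- as.numeric(rec)
    if (is.null(rate)) stop("rate must be given for bare numeric input", call. = FALSE)
  }
  samples <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(samples * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
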