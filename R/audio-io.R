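#' Load an audio file as a calibrated Waveform
#'
#' Reads a mono or stereo WAV (16/24-bit PCM or 32-bit float) or AIFF
#' (16/24-bit PCM) file, mixes stereo to mono by averaging, resamples to the
#' pipeline rate with a polyphase FIR resampler, and rescales the signal so
#' its RMS matches that of a pure tone at `levelDb` (peak amplitude
#' `dbSplToPascal(levelDb)`). Recorded audio carries no absolute pressure
#' calibration, so the level must be imposed.
#'
#' @param path path to a `.wav` or `.aif(f)` file.
#' @param rate target sampling rate, samples/s.
#' @param levelDb level to calibrate to, dB SPL.
#' @return a [Waveform-class].
#' @export
loadAudio <- function(path, rate = 1e5, levelDb = 60) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("unreadable or empty audio file: ", path)
  magic <- readBin(path, "raw", n = 4L)
  tag <- rawToChar(magic)
  parsed <- if (tag == "RIFF") readWavFile(path)
            else if (tag == "FORM") readAiffFile(path)
            else stop("unsupported audio container (expected WAV or AIFF): ",
                      path)
  x <- parsed$samples # channels in columns
  if (!nrow(x)) stop("audio file contains no samples: ", path)
  mono <- rowMeans(x)
  mono <- resampleTo(mono, parsed$rate, rate)
  target <- dbSplToPascal(levelDb) / sqrt(2)
  rms <- sqrt(mean(mono^2))
  if (rms > 0) mono <- mono * target / rms
  waveform(mono, rate)
}

## rational-factor polyphase resampling via signal::resample
resampleTo <- function(x, from, to) {
  if (from == to) return(x)
  ratio <- to / from
  # small rational approximation of the rate ratio
  best <- c(1L, 1L)
  bestErr <- Inf
  for (q in 1:500) {
    p <- round(ratio * q)
    if (p < 1) next
    err <- abs(p / q - ratio)
    if (err < bestErr - 1e-15) {
      best <- c(p, q)
      bestErr <- err
      if (err < 1e-12) break
    }
  }
  as.numeric(signal::resample(x, best[1L], best[2L]))
}

## minimal RIFF/WAVE reader: PCM 16/24-bit and IEEE float 32
readWavFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 4L, useBytes = TRUE) # "RIFF"
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (readChar(con, 4L, useBytes = TRUE) != "WAVE")
    stop("corrupted WAV file: ", path)
  fmt <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(sz) == 0) break
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE,
                         endian = "little"),
        channels = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        rate = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little")
      )
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
      if (sz %% 2L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data))
    stop("corrupted WAV file (missing fmt/data chunk): ", path)
  ch <- fmt$channels
  x <- if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data, "integer", length(data) / 2L, 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    int24ToDouble(data, endian = "little")
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data, "double", length(data) / 4L, 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ",
         fmt$bits, " bits)")
  }
  n <- length(x) %/% ch
  list(samples = matrix(x[seq_len(n * ch)], ncol = ch, byrow = TRUE),
       rate = fmt$rate)
}

## minimal AIFF reader: PCM 16/24-bit, big-endian
readAiffFile <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 4L, useBytes = TRUE) # "FORM"
  readBin(con, "integer", 1L, 4L, endian = "big")
  if (readChar(con, 4L, useBytes = TRUE) != "AIFF")
    stop("corrupted AIFF file: ", path)
  comm <- NULL
  data <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "big")
    if (length(sz) == 0) break
    if (id == "COMM") {
      raw <- readBin(con, "raw", sz + sz %% 2L)
      comm <- list(
        channels = readBin(raw[1:2], "integer", 1L, 2L, endian = "big"),
        bits = readBin(raw[7:8], "integer", 1L, 2L, endian = "big"),
        rate = extended80ToDouble(raw[9:18])
      )
    } else if (id == "SSND") {
      raw <- readBin(con, "raw", sz + sz %% 2L)
      offset <- readBin(raw[1:4], "integer", 1L, 4L, endian = "big")
      data <- raw[seq.int(9L + offset, length.out = sz - 8L - offset)]
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(comm) && !is.null(data)) break
  }
  if (is.null(comm) || is.null(data))
    stop("corrupted AIFF file (missing COMM/SSND chunk): ", path)
  x <- if (comm$bits == 16L) {
    readBin(data, "integer", length(data) / 2L, 2L, signed = TRUE,
            endian = "big") / 32768
  } else if (comm$bits == 24L) {
    int24ToDouble(data, endian = "big")
  } else {
    stop("unsupported AIFF sample size: ", comm$bits, " bits")
  }
  ch <- comm$channels
  n <- length(x) %/% ch
  list(samples = matrix(x[seq_len(n * ch)], ncol = ch, byrow = TRUE),
       rate = comm$rate)
}

## 24-bit signed PCM bytes -> doubles in [-1, 1)
int24ToDouble <- function(raw, endian) {
  n <- length(raw) %/% 3L
  m <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
  v <- if (endian == "little") {
    m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ]
  } else {
    m[3L, ] + 256 * m[2L, ] + 65536 * m[1L, ]
  }
  v[v >= 8388608] <- v[v >= 8388608] - 16777216
  v / 8388608
}

## IEEE 754 80-bit extended float (AIFF sample-rate field)
extended80ToDouble <- function(raw) {
  b <- as.integer(raw)
  sign <- ifelse(bitwAnd(b[1L], 128L) > 0L, -1, 1)
  expo <- bitwAnd(b[1L], 127L) * 256L + b[2L]
  mant <- 0
  for (i in 3:10) mant <- mant * 256 + b[i]
  if (expo == 0L && mant == 0) return(0)
  sign * mant * 2^(expo - 16383L - 63L)
}
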