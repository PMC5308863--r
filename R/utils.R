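#' Equivalent rectangular bandwidth (ERB)
#'
#' Glasberg-Moore ERB of the auditory filter at frequency `f`:
#' `24.7 * (4.37 * f/1000 + 1)` Hz (frequency entered in Hz, converted to kHz
#' internally).
#'
#' @param f frequency in Hz.
#' @return bandwidth in Hz.
#' @examples
#' erb(1000) # 132.639
#' @export
erb <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' ERB-number scale
#'
#' Maps frequency to its ERB number (cochlear place coordinate) and back.
#' `erbNumber` is `21.4 * log10(4.37 * f/1000 + 1)`; `erbToFreq` is its
#' inverse.
#'
#' @param f frequency in Hz.
#' @param e ERB number.
#' @return `erbNumber`: ERB number; `erbToFreq`: frequency in Hz.
#' @export
erbNumber <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname erbNumber
#' @export
erbToFreq <- function(e) 1000 * (10^(e / 21.4) - 1) / 4.37

#' Frequencies uniformly spaced on the ERB-number scale
#'
#' @param n number of points (>= 2).
#' @param fMin,fMax range endpoints in Hz (both included).
#' @return strictly increasing frequencies of length `n`.
#' @export
erbSpace <- function(n, fMin, fMax) {
  if (n < 2L) stop("'n' must be >= 2")
  f <- erbToFreq(seq(erbNumber(fMin), erbNumber(fMax), length.out = n))
  f[1L] <- fMin
  f[n] <- fMax
  f
}

#' Equal-tempered note name
#'
#' Nearest-semitone note name (A4 = 440 Hz convention).
#'
#' @param f frequency in Hz.
#' @return character vector of note names such as `"A5"`.
#' @examples
#' noteName(880) # "A5"
#' @export
noteName <- function(f) {
  names12 <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  n <- round(12 * log2(f / 440)) # semitones from A4
  midi <- n + 69L
  paste0(names12[(midi %% 12L) + 1L], midi %/% 12L - 1L)
}

## first-order low-pass (single real pole) applied down the rows of a matrix
lowpassOnePole <- function(x, cutoffHz, rate) {
  a <- exp(-2 * pi * cutoffHz / rate)
  b <- 1 - a
  if (is.matrix(x)) {
    apply(x, 2L, function(col) stats::filter(b * col, a, method = "recursive"))
  } else {
    as.numeric(stats::filter(b * x, a, method = "recursive"))
  }
}

## strict 3-point local maxima on a grid; plateaus take their left edge
localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

## deterministic content hash of an R object (used for dictionary caching)
contentHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
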