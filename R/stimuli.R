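#' @importFrom stats coefficients approx rnorm runif
#' @importFrom signal butter filter resample
#' @importClassesFrom Matrix Matrix
NULL

#' Convert a sound pressure level to a pascal amplitude
#'
#' Sound pressure level re 20 micropascals:
#' `20e-6 * 10^(levelDb / 20)` Pa.
#'
#' @param levelDb level in dB SPL.
#' @return amplitude in pascals.
#' @examples
#' dbSplToPascal(0)  # 2e-05
#' dbSplToPascal(30) # 6.3246e-04
#' @export
dbSplToPascal <- function(levelDb) {
  stopifnot(is.finite(levelDb))
  20e-6 * 10^(levelDb / 20)
}

#' Construct a Waveform from raw samples
#'
#' @param samples pressure samples in pascals.
#' @param rate sampling rate (samples/s); the pipeline default is 100 kHz.
#' @return a [Waveform-class].
#' @export
waveform <- function(samples, rate = 1e5) {
  new("Waveform", samples = as.numeric(samples), rate = rate)
}

#' Synthesize a (possibly shifted) harmonic complex
#'
#' Sum of sinusoids at frequencies `k * f0 + shift` for `k` in
#' `harmonics`, each with peak amplitude `dbSplToPascal(levelDb)` and the
#' given starting phase. With `shift = 0` the signal is periodic with period
#' `1/f0`; a nonzero shift produces the equally spaced inharmonic complexes
#' of the pitch-shift paradigm.
#'
#' @param f0 fundamental frequency, Hz.
#' @param harmonics integer harmonic numbers (>= 1); may be empty.
#' @param duration signal duration, s.
#' @param levelDb per-component level, dB SPL.
#' @param shift common frequency shift Delta-f, Hz.
#' @param phases per-component starting phases in radians (recycled;
#'   default 0, sine phase).
#' @param amplitudes optional per-component relative amplitude weights
#'   (recycled), multiplied onto the calibrated amplitude.
#' @param rate sampling rate, samples/s.
#' @return a [Waveform-class].
#' @examples
#' w <- makeHarmonicComplex(240, 1, duration = 0.015, levelDb = 30)
#' max(abs(samples(w))) # ~6.3e-4 Pa
#' @export
makeHarmonicComplex <- function(f0, harmonics, duration, levelDb = 30,
                                shift = 0, phases = 0, amplitudes = 1,
                                rate = 1e5) {
  stopifnot(f0 > 0, duration > 0)
  n <- round(duration * rate)
  if (!length(harmonics)) return(waveform(numeric(n), rate))
  harmonics <- as.integer(harmonics)
  stopifnot(all(harmonics >= 1L))
  freqs <- harmonics * f0 + shift
  if (any(freqs >= rate / 2))
    stop("component frequency at or above Nyquist: ", max(freqs), " Hz")
  phases <- rep_len(phases, length(freqs))
  amplitudes <- rep_len(amplitudes, length(freqs))
  t <- seq_len(n) / rate
  g <- dbSplToPascal(levelDb)
  s <- numeric(n)
  for (i in seq_along(freqs))
    s <- s + g * amplitudes[i] * sin(2 * pi * freqs[i] * t + phases[i])
  waveform(s, rate)
}

#' Synthesize a transposed tone
#'
#' For each carrier f_c the low-frequency modulator `sin(2*pi*f0*t)` is
#' half-wave rectified, low-pass filtered by a causal fourth-order
#' Butterworth at `0.2 * f_c`, and multiplied onto the carrier
#' `sin(2*pi*f_c*t)`; the products are summed and scaled so that each
#' component's amplitude equals `dbSplToPascal(levelDb)`. The construction
#' places the temporal pattern of a low-frequency tone at the high-CF
#' (basal) cochlear places tuned to the carriers.
#'
#' @param f0 modulator frequency, Hz.
#' @param duration duration, s.
#' @param levelDb level, dB SPL.
#' @param carriers carrier frequencies, Hz.
#' @param rate sampling rate, samples/s.
#' @return a [Waveform-class].
#' @export
makeTransposedTone <- function(f0, duration, levelDb = 30,
                               carriers = c(4000, 6350, 10080), rate = 1e5) {
  stopifnot(f0 >= 0, duration > 0, all(carriers < rate / 2))
  if (f0 > 0 && f0 >= 0.2 * min(carriers))
    stop("'f0' must be below 0.2 * min(carriers) for a transposed tone")
  n <- round(duration * rate)
  t <- seq_len(n) / rate
  mod <- pmax(0, sin(2 * pi * f0 * t))
  g <- dbSplToPascal(levelDb)
  s <- numeric(n)
  for (fc in carriers) {
    bf <- signal::butter(4, 0.2 * fc / (rate / 2), type = "low")
    modLp <- as.numeric(signal::filter(bf, mod))
    s <- s + g * modLp * sin(2 * pi * fc * t)
  }
  waveform(s, rate)
}

#' Synthesize iterated rippled noise (IRN)
#'
#' Seed-deterministic Gaussian white noise passed through `nIterations`
#' delay-and-add (`gain = +1`) or delay-and-subtract (`gain = -1`) stages
#' (s_i(t) = s_{i-1}(t) + gain * s_{i-1}(t - delay)), then low-pass filtered
#' (causal fourth-order Butterworth) and scaled so its RMS equals the RMS of
#' a pure tone of the requested level (peak amplitude
#' `dbSplToPascal(levelDb)`). Delay-and-add produces comb maxima at multiples
#' of `1/delay` and a pitch there; delay-and-subtract shifts the maxima by
#' `1/(2*delay)`.
#'
#' @param delay delay d, s.
#' @param duration duration, s (should exceed `nIterations * delay`).
#' @param levelDb level, dB SPL.
#' @param gain +1 (add) or -1 (subtract).
#' @param nIterations number of delay stages (>= 1).
#' @param seed integer RNG seed; the same seed reproduces the samples
#'   bitwise.
#' @param lowpassHz low-pass cutoff, Hz.
#' @param rate sampling rate, samples/s.
#' @return a [Waveform-class].
#' @export
makeIRN <- function(delay, duration, levelDb = 70, gain = 1,
                    nIterations = 1, seed = 1, lowpassHz = 4000, rate = 1e5) {
  stopifnot(delay > 0, duration > 0, gain %in% c(1, -1), nIterations >= 1)
  n <- round(duration * rate)
  dSamp <- round(delay * rate)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  s <- rnorm(n)
  for (i in seq_len(nIterations)) {
    delayed <- c(numeric(dSamp), s[seq_len(n - dSamp)])
    s <- s + gain * delayed
  }
  bf <- signal::butter(4, lowpassHz / (rate / 2), type = "low")
  s <- as.numeric(signal::filter(bf, s))
  target <- dbSplToPascal(levelDb) / sqrt(2) # RMS of a calibrated tone
  rms <- sqrt(mean(s^2))
  if (rms > 0) s <- s * target / rms
  waveform(s, rate)
}
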