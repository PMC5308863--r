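#' Create an auditory periphery configuration
#'
#' @param nChannels number of CF channels (N).
#' @param cfMin,cfMax CF range, Hz.
#' @param mode `"linear"` or `"saturating"` (adds a memoryless tanh
#'   compression of the basilar-membrane signal before the hair-cell stage,
#'   emulating high-level saturation and the accompanying spatial spread of
#'   excitation).
#' @param ihcCutoff inner-hair-cell low-pass cutoff, Hz.
#' @param satKnee half-saturation pressure of the compressive stage, Pa.
#' @param simDuration simulated duration T_a, s.
#' @param windowDuration analysis window T kept from the end, s.
#' @return a [PeripheryConfig-class].
#' @export
peripheryConfig <- function(nChannels = 200, cfMin = 125, cfMax = 20000,
                            mode = c("linear", "saturating"),
                            ihcCutoff = 1000, satKnee = 0.01,
                            simDuration = 0.015, windowDuration = 0.005) {
  new("PeripheryConfig",
      nChannels = as.integer(nChannels), cfMin = cfMin, cfMax = cfMax,
      mode = match.arg(mode), ihcCutoff = ihcCutoff, satKnee = satKnee,
      simDuration = simDuration, windowDuration = windowDuration)
}

#' Characteristic-frequency grid of a periphery configuration
#'
#' `nChannels` frequencies uniformly spaced on the ERB-number scale between
#' `cfMin` and `cfMax`, so channel density follows cochlear frequency
#' resolution.
#'
#' @param config a [PeripheryConfig-class].
#' @return ascending CFs in Hz.
#' @export
cfGrid <- function(config) {
  erbSpace(config@nChannels, config@cfMin, config@cfMax)
}

## Precomputed gammatone filterbank kernel: FFTs of the channel impulse
## responses, unit gain at CF. Cached per (config, rate, nSamples).
.kernelCache <- new.env(parent = emptyenv())

anKernel <- function(config, rate, nSamples) {
  key <- contentHash(list(config, rate, nSamples))
  hit <- .kernelCache[[key]]
  if (!is.null(hit)) return(hit)
  cf <- cfGrid(config)
  nfft <- stats::nextn(2L * nSamples - 1L, 2L)
  t <- seq_len(nSamples) / rate
  irf <- matrix(0 + 0i, nfft, length(cf))
  for (j in seq_along(cf)) {
    b <- 1.019 * erb(cf[j])
    g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf[j] * t)
    gain <- Mod(sum(g * exp(-2i * pi * cf[j] * t)))
    g <- g / gain
    irf[, j] <- stats::fft(c(g, numeric(nfft - nSamples)))
  }
  out <- list(irf = irf, cf = cf, nfft = nfft, n = nSamples)
  .kernelCache[[key]] <- out
  out
}

## gammatone filterbank via FFT convolution; returns nSamples x N matrix
gammatoneFilter <- function(x, kernel) {
  sf <- stats::fft(c(x, numeric(kernel$nfft - length(x))))
  y <- kernel$irf * sf
  y <- Re(stats::mvfft(y, inverse = TRUE)) / kernel$nfft
  y[seq_len(kernel$n), , drop = FALSE]
}

#' Simulate the auditory-nerve population response
#'
#' Runs the simplified periphery on a calibrated waveform: per channel, a
#' fourth-order gammatone filter at its CF (bandwidth 1.019 ERB, unit gain
#' at CF), optional compressive saturation (`"saturating"` mode,
#' `knee * tanh(x / knee)`), half-wave rectification, and a first-order
#' low-pass at the inner-hair-cell cutoff. The last `windowDuration` seconds
#' are kept (the discarded prefix doubles as filter settling time) and the
#' matrix is divided by its global maximum so the peak entry is 1. An
#' all-zero input returns a zero matrix flagged as unnormalized.
#'
#' @param wave a [Waveform-class] at least `simDuration` long (the final
#'   `simDuration` seconds are used).
#' @param config a [PeripheryConfig-class].
#' @return an [ANResponse-class].
#' @export
simulateAN <- function(wave, config = peripheryConfig()) {
  stopifnot(is(wave, "Waveform"), is(config, "PeripheryConfig"))
  rate <- wave@rate
  nSim <- round(config@simDuration * rate)
  if (length(wave@samples) < nSim)
    stop("waveform shorter than the configured simDuration")
  x <- utils::tail(wave@samples, nSim)
  kernel <- anKernel(config, rate, nSim)
  bm <- gammatoneFilter(x, kernel)
  if (config@mode == "saturating")
    bm <- config@satKnee * tanh(bm / config@satKnee)
  rect <- pmax(bm, 0)
  ihc <- lowpassOnePole(rect, config@ihcCutoff, rate)
  nWin <- round(config@windowDuration * rate)
  win <- ihc[seq.int(nSim - nWin + 1L, nSim), , drop = FALSE]
  peak <- max(abs(win))
  if (peak > 0) {
    win <- win / peak
    normalized <- TRUE
  } else {
    normalized <- FALSE
  }
  new("ANResponse", rates = win, cfs = kernel$cf, rate = rate,
      normalized = normalized)
}

#' Vectorize an auditory-nerve response
#'
#' Column-major stacking of the time-by-channel rate matrix into the vector
#' consumed by the sparse coder; `matrix(v, nrow(rates))` inverts it exactly.
#'
#' @param resp an [ANResponse-class].
#' @return numeric vector of length `T * N`.
#' @export
vectorizeResponse <- function(resp) {
  stopifnot(is(resp, "ANResponse"))
  as.numeric(resp@rates)
}

#' Save / load an ANResponse
#'
#' Round-trips the rate matrix, CF vector and metadata through a serialized
#' array container on disk.
#'
#' @param resp an [ANResponse-class].
#' @param path file path.
#' @return `readANResponse`: the restored [ANResponse-class];
#'   `writeANResponse`: `path`, invisibly.
#' @export
writeANResponse <- function(resp, path) {
  stopifnot(is(resp, "ANResponse"))
  saveRDS(list(rates = resp@rates, cfs = resp@cfs, rate = resp@rate,
               normalized = resp@normalized), path)
  invisible(path)
}

#' @rdname writeANResponse
#' @export
readANResponse <- function(path) {
  x <- readRDS(path)
  new("ANResponse", rates = x$rates, cfs = x$cfs, rate = x$rate,
      normalized = x$normalized)
}
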