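#' Full pitch pipeline for one stimulus
#'
#' Convenience wrapper chaining periphery simulation, sparse coding, group
#' collapsing, coefficient interpolation, and the harmonic sieve. The
#' periphery configuration is taken from the dictionary so stimulus and
#' atoms share one front end; by default the solver normalizes the target
#' and atom columns to unit Euclidean norm (see [SolverConfig-class]).
#'
#' @param wave a [Waveform-class].
#' @param dict a [Dictionary-class].
#' @param sieve a [SieveMatrix-class] on [sieveGrid()] of the dictionary.
#' @param solver a [SolverConfig-class].
#' @param config optional [PeripheryConfig-class] overriding the
#'   dictionary's (e.g. to force saturating mode for a loud stimulus).
#' @param source provenance list carried into the resulting density.
#' @return a list with elements `pdf` ([PitchPDF-class]), `code`
#'   ([SparseCode-class]) and `resp` ([ANResponse-class]).
#' @examples
#' \donttest{
#' cfg <- peripheryConfig(nChannels = 60)
#' dict <- buildSineDictionary(M = 80, freqRange = c(125, 4000), config = cfg)
#' sv <- buildSieve(sieveGrid(dict), fMax = 4000)
#' w <- makeHarmonicComplex(225, 3:8, duration = 0.015, levelDb = 30)
#' res <- pitchFromWaveform(w, dict, sv)
#' estimatePitch(res$pdf)$fHat
#' }
#' @export
pitchFromWaveform <- function(wave, dict, sieve,
                              solver = solverConfig(normalize = TRUE),
                              config = NULL, source = list()) {
  stopifnot(is(dict, "Dictionary"), is(sieve, "SieveMatrix"))
  if (is.null(config)) config <- dict@peripheryConfig
  resp <- simulateAN(wave, config)
  v <- vectorizeResponse(resp)
  code <- fitSparseCode(v, dict, solver)
  hT <- interpolateCoefficients(code@h, dict@freqs, sieve@grid)
  pdf <- computePdf(hT, sieve,
                    source = c(source, list(lambda = solver@lambda)))
  list(pdf = pdf, code = code, resp = resp)
}
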