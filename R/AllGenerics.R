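#' @name accessors
#' @title Accessors for sparsepitch classes
#' @description Slot accessors. `samples`/`sampleRate`/`durationSec` read a
#'   [Waveform-class]; `anRates`/`cfs` read an [ANResponse-class];
#'   `atomMatrix`/`atomFreqs`/`nGroups`/`groupPhases`/`atomFamily` read a
#'   [Dictionary-class]; `pitchGrid`/`pitchProbs` read a [PitchPDF-class] or
#'   [SieveMatrix-class]; `sieveWeights`/`sieveSigmas` read a
#'   [SieveMatrix-class]; `coefficients`/`groupedCoefficients` read a
#'   [SparseCode-class].
#' @param object an object of the documented class.
#' @param x an object (for `coefficients`).
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("durationSec", function(object) standardGeneric("durationSec"))
#' @rdname accessors
#' @export
setGeneric("anRates", function(object) standardGeneric("anRates"))
#' @rdname accessors
#' @export
setGeneric("cfs", function(object) standardGeneric("cfs"))
#' @rdname accessors
#' @export
setGeneric("atomMatrix", function(object) standardGeneric("atomMatrix"))
#' @rdname accessors
#' @export
setGeneric("atomFreqs", function(object) standardGeneric("atomFreqs"))
#' @rdname accessors
#' @export
setGeneric("nGroups", function(object) standardGeneric("nGroups"))
#' @rdname accessors
#' @export
setGeneric("groupPhases", function(object) standardGeneric("groupPhases"))
#' @rdname accessors
#' @export
setGeneric("atomFamily", function(object) standardGeneric("atomFamily"))
#' @rdname accessors
#' @export
setGeneric("pitchGrid", function(object) standardGeneric("pitchGrid"))
#' @rdname accessors
#' @export
setGeneric("pitchProbs", function(object) standardGeneric("pitchProbs"))
#' @rdname accessors
#' @export
setGeneric("sieveWeights", function(object) standardGeneric("sieveWeights"))
#' @rdname accessors
#' @export
setGeneric("sieveSigmas", function(object) standardGeneric("sieveSigmas"))
#' @rdname accessors
#' @export
setGeneric("groupedCoefficients",
           function(object) standardGeneric("groupedCoefficients"))

setMethod("samples", "Waveform", function(object) object@samples)
setMethod("sampleRate", "Waveform", function(object) object@rate)
setMethod("durationSec", "Waveform",
          function(object) length(object@samples) / object@rate)
setMethod("anRates", "ANResponse", function(object) object@rates)
setMethod("cfs", "ANResponse", function(object) object@cfs)
setMethod("atomMatrix", "Dictionary", function(object) object@atoms)
setMethod("atomFreqs", "Dictionary", function(object) object@freqs)
setMethod("nGroups", "Dictionary", function(object) object@nGroups)
setMethod("groupPhases", "Dictionary", function(object) object@phases)
setMethod("atomFamily", "Dictionary", function(object) object@family)
setMethod("pitchGrid", "PitchPDF", function(object) object@grid)
setMethod("pitchGrid", "SieveMatrix", function(object) object@grid)
setMethod("pitchProbs", "PitchPDF", function(object) object@probs)
setMethod("sieveWeights", "SieveMatrix", function(object) object@weights)
setMethod("sieveSigmas", "SieveMatrix", function(object) object@sigmas)
setMethod("groupedCoefficients", "SparseCode",
          function(object) object@hGrouped)

#' @rdname accessors
#' @export
setMethod("coefficients", "SparseCode", function(object, ...) object@h)

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.1f ms), peak %.3g Pa\n",
              length(object@samples), object@rate,
              1000 * durationSec(object),
              if (length(object@samples)) max(abs(object@samples)) else 0))
})

setMethod("show", "PeripheryConfig", function(object) {
  cat(sprintf(
    "PeripheryConfig: %d channels, CF %g-%g Hz, mode \"%s\"\n",
    object@nChannels, object@cfMin, object@cfMax, object@mode))
  cat(sprintf("  IHC low-pass %g Hz; window %g of %g ms\n",
              object@ihcCutoff, 1000 * object@windowDuration,
              1000 * object@simDuration))
})

setMethod("show", "ANResponse", function(object) {
  cat(sprintf(
    "ANResponse: %d time samples x %d channels (CF %.4g-%.5g Hz)%s\n",
    nrow(object@rates), ncol(object@rates),
    min(object@cfs), max(object@cfs),
    if (object@normalized) ", peak-normalized" else " (all-zero input)"))
})

setMethod("show", "Dictionary", function(object) {
  cat(sprintf(
    "Dictionary (\"%s\"): %d frequencies x %d phase group(s) = %d atoms of dim %d\n",
    object@family, length(object@freqs), object@nGroups,
    ncol(object@atoms), nrow(object@atoms)))
  cat(sprintf("  f_d %.4g-%.5g Hz; periphery: %d channels, mode \"%s\"\n",
              min(object@freqs), max(object@freqs),
              object@peripheryConfig@nChannels, object@peripheryConfig@mode))
})

setMethod("show", "SparseCode", function(object) {
  cat(sprintf(
    "SparseCode: %d coefficients (%d nonzero), lambda %g, %d iterations%s\n",
    length(object@h), sum(object@h > 0), object@lambda, object@nIter,
    if (object@converged) "" else " [not converged]"))
})

setMethod("show", "SieveMatrix", function(object) {
  cat(sprintf(
    "SieveMatrix: %d candidate pitches %.4g-%.5g Hz, %d template weights\n",
    length(object@grid), min(object@grid), max(object@grid),
    length(object@weights@x)))
})

setMethod("show", "PitchPDF", function(object) {
  if (object@noPitch) {
    cat("PitchPDF: no-pitch (uniform) density over",
        length(object@grid), "candidates\n")
  } else {
    cat(sprintf("PitchPDF: %d candidates, argmax %.4g Hz\n",
                length(object@grid), object@grid[which.max(object@probs)]))
  }
})
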