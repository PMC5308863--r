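#' @import methods
#' @importFrom Matrix sparseMatrix crossprod t
NULL

#' Calibrated pressure waveform
#'
#' A mono acoustic signal in pascals at a fixed sampling rate. All stimulus
#' generators return this class; the auditory periphery consumes it.
#'
#' @slot samples numeric vector of instantaneous pressure (Pa).
#' @slot rate sampling rate in samples per second.
#'
#' @seealso [makeHarmonicComplex()], [makeTransposedTone()], [makeIRN()],
#'   [loadAudio()]
#' @export
setClass("Waveform",
  representation(samples = "numeric", rate = "numeric"),
  prototype(samples = numeric(0), rate = 1e5)
)

setValidity("Waveform", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive finite number")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  if (length(msg)) msg else TRUE
})

#' Auditory periphery configuration
#'
#' Parameters of the simplified auditory-nerve front end: a bank of
#' fourth-order gammatone filters on an ERB-number-spaced grid of
#' characteristic frequencies (CFs), an inner-hair-cell stage (half-wave
#' rectification followed by a first-order low-pass that removes fine
#' structure above roughly 1 kHz, mimicking the loss of phase locking), and an
#' optional memoryless compressive saturation engaged at high sound levels.
#'
#' @slot nChannels number of CF channels (N).
#' @slot cfMin,cfMax CF range in Hz.
#' @slot mode `"linear"` or `"saturating"`.
#' @slot ihcCutoff inner-hair-cell low-pass cutoff, Hz.
#' @slot satKnee half-saturation pressure of the compressive stage, Pa. The
#'   default 0.01 Pa (~54 dB SPL) leaves a 30 dB SPL tone in the near-linear
#'   region while a 90 dB SPL tone is strongly saturated.
#' @slot simDuration total simulated duration in seconds (stimulus tail fed to
#'   the filterbank; the leading part doubles as filter settling time).
#' @slot windowDuration duration in seconds of the final analysis window kept
#'   from the end of the simulation.
#'
#' @seealso [peripheryConfig()], [simulateAN()]
#' @export
setClass("PeripheryConfig",
  representation(
    nChannels = "integer", cfMin = "numeric", cfMax = "numeric",
    mode = "character", ihcCutoff = "numeric", satKnee = "numeric",
    simDuration = "numeric", windowDuration = "numeric"
  ),
  prototype(
    nChannels = 200L, cfMin = 125, cfMax = 20000, mode = "linear",
    ihcCutoff = 1000, satKnee = 0.01, simDuration = 0.015,
    windowDuration = 0.005
  )
)

setValidity("PeripheryConfig", function(object) {
  msg <- character(0)
  if (object@nChannels < 2L) msg <- c(msg, "'nChannels' must be >= 2")
  if (!(object@cfMin > 0 && object@cfMin < object@cfMax))
    msg <- c(msg, "need 0 < cfMin < cfMax")
  if (!object@mode %in% c("linear", "saturating"))
    msg <- c(msg, "'mode' must be \"linear\" or \"saturating\"")
  if (object@windowDuration > object@simDuration)
    msg <- c(msg, "'windowDuration' must not exceed 'simDuration'")
  if (object@ihcCutoff <= 0) msg <- c(msg, "'ihcCutoff' must be positive")
  if (object@satKnee <= 0) msg <- c(msg, "'satKnee' must be positive")
  if (length(msg)) msg else TRUE
})

#' Spatiotemporal auditory-nerve response
#'
#' The time-by-channel matrix of normalized instantaneous auditory-nerve
#' rates S_AN(t, f_CF) produced by [simulateAN()]. Rows are time samples of
#' the analysis window, columns are CF channels in ascending CF order. For a
#' nonzero stimulus the matrix is divided by its global maximum so the peak
#' entry is 1.
#'
#' @slot rates numeric matrix, time samples x channels.
#' @slot cfs ascending characteristic frequencies (Hz), one per column.
#' @slot rate sampling rate of the time axis (samples/s).
#' @slot normalized logical; `FALSE` only for an all-zero input.
#' @export
setClass("ANResponse",
  representation(
    rates = "matrix", cfs = "numeric", rate = "numeric",
    normalized = "logical"
  )
)

setValidity("ANResponse", function(object) {
  msg <- character(0)
  if (ncol(object@rates) != length(object@cfs))
    msg <- c(msg, "ncol(rates) must equal length(cfs)")
  if (is.unsorted(object@cfs, strictly = TRUE))
    msg <- c(msg, "'cfs' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Dictionary of auditory-nerve response atoms
#'
#' Columns are vectorized, peak-normalized AN responses to probe stimuli
#' (pure tones for the `"sine"` family, six-harmonic complexes with 1/k
#' amplitudes for the `"stack"` family). With `nGroups` (g) > 1 each atom
#' frequency is represented by g atoms that differ only in the probe's
#' starting phase (phi_k = 2*pi*k/g); the g columns of a group are contiguous,
#' so column (m-1)*g + j holds frequency m, phase j.
#'
#' @slot atoms numeric matrix, (T*N) x (g*M).
#' @slot freqs ascending atom frequencies f_d (Hz), length M.
#' @slot nGroups number of phases per frequency group (g).
#' @slot phases the g probe phases in radians.
#' @slot family `"sine"` or `"stack"`.
#' @slot levels probe level(s) in dB SPL actually used per atom frequency.
#' @slot peripheryConfig the [PeripheryConfig-class] used to build the atoms.
#' @slot rate sampling rate used for the probes.
#' @export
setClass("Dictionary",
  representation(
    atoms = "matrix", freqs = "numeric", nGroups = "integer",
    phases = "numeric", family = "character", levels = "numeric",
    peripheryConfig = "PeripheryConfig", rate = "numeric"
  )
)

setValidity("Dictionary", function(object) {
  msg <- character(0)
  if (ncol(object@atoms) != length(object@freqs) * object@nGroups)
    msg <- c(msg, "ncol(atoms) must equal length(freqs) * nGroups")
  if (is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "'freqs' must be strictly increasing")
  if (!object@family %in% c("sine", "stack"))
    msg <- c(msg, "'family' must be \"sine\" or \"stack\"")
  if (length(object@phases) != object@nGroups)
    msg <- c(msg, "'phases' must have length nGroups")
  if (ncol(object@atoms)) {
    peaks <- apply(abs(object@atoms), 2L, max)
    if (any(peaks < 0.999) || any(peaks > 1.001))
      msg <- c(msg, "every atom column must be peak-normalized to 1")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse coder configuration
#'
#' Settings of the iterative soft-thresholding (ISTA) solver for the
#' L1-regularized reconstruction. `alpha = "auto"` estimates the largest
#' eigenvalue of D'D by power iteration (inflated by 5%), the condition that
#' guarantees monotone descent.
#'
#' @slot lambda L1 penalty weight (>= 0); 0 selects the least-squares mode.
#' @slot maxIter iteration cap.
#' @slot tol relative objective-change stopping threshold (for `lambda` = 0,
#'   a relative gradient-norm threshold).
#' @slot alpha step-size scalar, or NA for `"auto"`.
#' @slot nonneg `"clamp"` (signed iteration, negatives clamped at exit) or
#'   `"onesided"` (one-sided shrinkage max(0, x - t) throughout).
#' @slot normalize logical; if TRUE the solver rescales the target and the
#'   atom columns to unit Euclidean norm before iterating (the coefficient
#'   vector is reported in the normalized coordinates). This makes `lambda`
#'   comparable across stimuli and dictionary presets; the pipeline uses it.
#' @export
setClass("SolverConfig",
  representation(
    lambda = "numeric", maxIter = "integer", tol = "numeric",
    alpha = "numeric", nonneg = "character", normalize = "logical"
  ),
  prototype(
    lambda = 0.01, maxIter = 5000L, tol = 1e-6, alpha = NA_real_,
    nonneg = "clamp", normalize = FALSE
  )
)

setValidity("SolverConfig", function(object) {
  msg <- character(0)
  if (object@lambda < 0) msg <- c(msg, "'lambda' must be >= 0")
  if (object@maxIter < 1L) msg <- c(msg, "'maxIter' must be >= 1")
  if (!object@nonneg %in% c("clamp", "onesided"))
    msg <- c(msg, "'nonneg' must be \"clamp\" or \"onesided\"")
  if (length(msg)) msg else TRUE
})

#' Sparse coefficient vector
#'
#' Result of [fitSparseCode()]: the group-resolved nonnegative coefficient
#' vector (length g*M) and its group-collapsed form (length M, per-group
#' sums), along with the final penalized objective
#' 0.5*||v - D h||^2 + (lambda/2)*||h||_1 and the solver trace.
#'
#' @slot hGrouped nonnegative coefficients, one per atom column (length g*M).
#' @slot h group-collapsed coefficients, one per atom frequency (length M).
#' @slot objective final objective value.
#' @slot nIter iterations used.
#' @slot converged logical; FALSE if the iteration cap was hit.
#' @slot lambda penalty used.
#' @slot trace objective value per iteration.
#' @export
setClass("SparseCode",
  representation(
    hGrouped = "numeric", h = "numeric", objective = "numeric",
    nIter = "integer", converged = "logical", lambda = "numeric",
    trace = "numeric"
  )
)

setValidity("SparseCode", function(object) {
  if (length(object@h) && min(object@h) < 0)
    "collapsed coefficients must be nonnegative" else TRUE
})

#' Gaussian harmonic sieve
#'
#' A bank of harmonic templates over a dense candidate-pitch grid. Row i
#' holds unnormalized Gaussians of width sigma_i = 0.2 * ERB(f_i) centered on
#' the integer multiples n*f_i (n*f_i <= the grid ceiling) of the candidate
#' pitch f_i, where ERB(f) = 24.7 * (4.37*f/1000 + 1) Hz.
#'
#' @slot grid ascending candidate pitches f_p in Hz, length P.
#' @slot weights P x P sparse nonnegative template matrix G.
#' @slot sigmas per-row Gaussian widths sigma_i (Hz).
#' @slot fMax harmonic ceiling in Hz (templates stop at n*f_i <= fMax).
#' @export
setClass("SieveMatrix",
  representation(
    grid = "numeric", weights = "Matrix", sigmas = "numeric", fMax = "numeric"
  )
)

setValidity("SieveMatrix", function(object) {
  msg <- character(0)
  if (is.unsorted(object@grid, strictly = TRUE))
    msg <- c(msg, "'grid' must be strictly increasing")
  if (nrow(object@weights) != length(object@grid) ||
      ncol(object@weights) != length(object@grid))
    msg <- c(msg, "'weights' must be P x P with P = length(grid)")
  if (length(object@sigmas) != length(object@grid))
    msg <- c(msg, "'sigmas' must have length P")
  if (length(msg)) msg else TRUE
})

#' Pitch probability density
#'
#' A unit-sum probability vector over the sieve's candidate-pitch grid,
#' produced by [computePdf()]. If the coefficient input was entirely zero the
#' density is uniform and `noPitch` is TRUE.
#'
#' @slot grid candidate pitches (Hz).
#' @slot probs nonnegative, unit-sum probabilities.
#' @slot noPitch logical flag for the degenerate all-zero input.
#' @slot source free-form provenance list (stimulus id, lambda, ...).
#' @export
setClass("PitchPDF",
  representation(
    grid = "numeric", probs = "numeric", noPitch = "logical", source = "list"
  ),
  prototype(noPitch = FALSE, source = list())
)

setValidity("PitchPDF", function(object) {
  msg <- character(0)
  if (length(object@probs) != length(object@grid))
    msg <- c(msg, "'probs' and 'grid' must have the same length")
  if (length(object@probs)) {
    if (min(object@probs) < 0) msg <- c(msg, "'probs' must be nonnegative")
    if (abs(sum(object@probs) - 1) > 1e-9)
      msg <- c(msg, "'probs' must sum to 1 (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})
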