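#' Interpolate sparse coefficients onto the dense pitch grid
#'
#' Linear interpolation of the collapsed coefficient vector (one value per
#' atom frequency) onto the sieve's candidate-pitch grid; values outside the
#' dictionary's frequency range are zero and negatives are clipped at zero.
#'
#' @param h numeric coefficients, length M.
#' @param dictFreqs ascending atom frequencies, length M.
#' @param grid dense target grid (length P >= M), covering `dictFreqs`.
#' @return interpolated nonnegative vector of length P.
#' @export
interpolateCoefficients <- function(h, dictFreqs, grid) {
  if (length(h) != length(dictFreqs))
    stop("length(h) must equal length(dictFreqs)")
  if (length(grid) < length(h))
    stop("grid must be at least as long as h")
  if (all(h == 0)) return(numeric(length(grid)))
  y <- approx(dictFreqs, h, xout = grid, rule = 1)$y
  y[is.na(y)] <- 0
  pmax(y, 0)
}

#' Default candidate-pitch grid for a dictionary
#'
#' `P = 15 * M` frequencies on the ERB-number scale spanning the atom
#' frequency range.
#'
#' @param dict a [Dictionary-class] (or a numeric frequency vector).
#' @param perAtom grid points per atom frequency.
#' @return ascending grid of length `15 * M`.
#' @export
sieveGrid <- function(dict, perAtom = 15) {
  freqs <- if (is(dict, "Dictionary")) dict@freqs else dict
  erbSpace(perAtom * length(freqs), min(freqs), max(freqs))
}

#' Build the Gaussian harmonic sieve matrix
#'
#' Row i of the P x P matrix holds unnormalized Gaussians
#' `G[i, j] = sum_n exp(-(f_j - n * f_i)^2 / (2 * sigma_i^2))` over the
#' integer harmonics `n * f_i <= fMax` of candidate pitch f_i, with
#' `sigma_i = 0.2 * ERB(f_i)`. Entries beyond `truncate` standard deviations
#' from every harmonic are dropped, keeping the matrix sparse.
#'
#' @param grid ascending candidate pitches, Hz.
#' @param fMax harmonic ceiling, Hz.
#' @param truncate Gaussian truncation radius in standard deviations.
#' @return a [SieveMatrix-class].
#' @examples
#' sv <- buildSieve(erbSpace(300, 125, 2000), fMax = 4000)
#' @export
buildSieve <- function(grid, fMax = 20000, truncate = 5) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly increasing")
  P <- length(grid)
  sigmas <- 0.2 * erb(grid)
  iList <- vector("list", P)
  jList <- vector("list", P)
  xList <- vector("list", P)
  for (i in seq_len(P)) {
    fi <- grid[i]
    si <- sigmas[i]
    nMax <- floor(fMax / fi)
    js <- integer(0)
    xs <- numeric(0)
    for (n in seq_len(nMax)) {
      ctr <- n * fi
      lo <- findInterval(ctr - truncate * si, grid) + 1L
      hi <- findInterval(ctr + truncate * si, grid)
      if (hi < lo) next
      jj <- lo:hi
      js <- c(js, jj)
      xs <- c(xs, exp(-(grid[jj] - ctr)^2 / (2 * si^2)))
    }
    if (length(js)) {
      iList[[i]] <- rep.int(i, length(js))
      jList[[i]] <- js
      xList[[i]] <- xs
    }
  }
  W <- Matrix::sparseMatrix(
    i = unlist(iList), j = unlist(jList), x = unlist(xList),
    dims = c(P, P))
  new("SieveMatrix", grid = grid, weights = W, sigmas = sigmas, fMax = fMax)
}

#' Compute the pitch probability density
#'
#' Applies the harmonic sieve to the interpolated coefficient vector:
#' `p = G %*% hTilde`, normalized by its entry sum to a unit-sum density.
#' A candidate pitch whose harmonic template aligns with the nonzero
#' coefficients scores high. An all-zero input yields a uniform density
#' flagged as `noPitch`.
#'
#' @param hTilde nonnegative coefficient vector on the sieve grid (length
#'   P), e.g. from [interpolateCoefficients()].
#' @param sieve a [SieveMatrix-class].
#' @param source optional provenance list stored in the result.
#' @return a [PitchPDF-class].
#' @export
computePdf <- function(hTilde, sieve, source = list()) {
  stopifnot(is(sieve, "SieveMatrix"))
  if (length(hTilde) != length(sieve@grid))
    stop("length(hTilde) must equal the sieve grid length")
  if (any(hTilde < 0)) stop("'hTilde' must be nonnegative")
  P <- length(hTilde)
  if (all(hTilde == 0)) {
    return(new("PitchPDF", grid = sieve@grid, probs = rep(1 / P, P),
               noPitch = TRUE, source = source))
  }
  p <- as.numeric(sieve@weights %*% hTilde)
  probs <- p / sum(p)
  # guard the unit-sum invariant against accumulated roundoff
  probs <- probs / sum(probs)
  new("PitchPDF", grid = sieve@grid, probs = probs, noPitch = FALSE,
      source = source)
}

#' One-octave interval around a reference frequency
#'
#' The geometric +/- 0.5 octave window `[fRef / sqrt(2), fRef * sqrt(2)]`
#' used to restrict pitch readout, as in standard psychoacoustic practice.
#'
#' @param fRef reference frequency, Hz.
#' @return numeric length-2 interval.
#' @export
octaveInterval <- function(fRef) c(fRef / sqrt(2), fRef * sqrt(2))

#' Estimate the pitch from a probability density
#'
#' The estimate is the grid argmax of the density (over the whole grid, or
#' over `restrict` when a frequency interval is given). Local maxima (strict
#' 3-point maxima; plateaus take their left edge) are also returned ranked
#' by height. Exact ties take the lower frequency (and are messaged).
#'
#' @param pdf a [PitchPDF-class].
#' @param restrict optional `c(lo, hi)` interval in Hz, e.g.
#'   [octaveInterval()].
#' @return a list with elements `fHat` (Hz), `peaks` (data.frame with
#'   columns `freq`, `height`, ranked by descending height) and `tie`
#'   (logical).
#' @export
estimatePitch <- function(pdf, restrict = NULL) {
  stopifnot(is(pdf, "PitchPDF"))
  sel <- seq_along(pdf@grid)
  if (!is.null(restrict)) {
    stopifnot(length(restrict) == 2L)
    sel <- which(pdf@grid >= restrict[1L] & pdf@grid <= restrict[2L])
    if (!length(sel)) stop("empty restriction interval")
  }
  probs <- pdf@probs[sel]
  top <- max(probs)
  tie <- sum(probs == top) > 1L
  if (tie) message("pitch estimate tie; returning the lower frequency")
  fHat <- pdf@grid[sel[which.max(probs)]]
  lm <- localMaxima(probs)
  ord <- order(probs[lm], decreasing = TRUE)
  peaks <- data.frame(freq = pdf@grid[sel[lm[ord]]], height = probs[lm[ord]])
  list(fHat = fHat, peaks = peaks, tie = tie)
}

#' Pitch salience: ratio of the two highest peaks in one octave
#'
#' The height of the highest local maximum of the density within the given
#' one-octave interval divided by the height of the second highest. A
#' unimodal density gives `Inf` (maximally salient: no competing pitch).
#'
#' @param pdf a [PitchPDF-class].
#' @param interval `c(lo, hi)` in Hz, typically [octaveInterval()] around
#'   the nominal pitch.
#' @return salience ratio (>= 1), possibly `Inf`.
#' @export
pitchSalience <- function(pdf, interval) {
  est <- estimatePitch(pdf, restrict = interval)
  if (nrow(est$peaks) < 2L) return(Inf)
  est$peaks$height[1L] / est$peaks$height[2L]
}

#' Export a pitch density as CSV, or summarize it as a list
#'
#' @param pdf a [PitchPDF-class].
#' @param path output CSV path (columns `grid_hz`, `prob`).
#' @param restrict optional readout interval for the summary.
#' @param nPeaks number of ranked peaks to keep in the summary.
#' @return `exportPdf`: `path` invisibly. `pitchSummary`: a list with
#'   `f_hat`, `peaks` and `salience`, ready for JSON serialization.
#' @export
exportPdf <- function(pdf, path) {
  stopifnot(is(pdf, "PitchPDF"))
  utils::write.csv(data.frame(grid_hz = pdf@grid, prob = pdf@probs),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname exportPdf
#' @export
pitchSummary <- function(pdf, restrict = NULL, nPeaks = 4) {
  est <- estimatePitch(pdf, restrict = restrict)
  sal <- if (nrow(est$peaks) >= 2L)
    est$peaks$height[1L] / est$peaks$height[2L] else Inf
  list(f_hat = est$fHat,
       peaks = utils::head(est$peaks, nPeaks),
       salience = sal,
       no_pitch = pdf@noPitch)
}
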