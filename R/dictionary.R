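## in-session dictionary cache (disk cache optional, keyed by content hash)
.dictCache <- new.env(parent = emptyenv())

buildDictionary <- function(freqs, g, levelsDb, family, config, rate,
                            stackHarmonics = 6L, cacheDir = NULL) {
  phases <- 2 * pi * (seq_len(g) - 1L) / g
  key <- contentHash(list(freqs, phases, levelsDb, family, config, rate,
                          stackHarmonics))
  hit <- .dictCache[[key]]
  if (!is.null(hit)) return(hit)
  if (!is.null(cacheDir)) {
    fp <- file.path(cacheDir, paste0("dict-", key, ".rds"))
    if (file.exists(fp)) {
      dict <- readRDS(fp)
      .dictCache[[key]] <- dict
      return(dict)
    }
  }
  nSim <- round(config@simDuration * rate)
  nWin <- round(config@windowDuration * rate)
  atoms <- matrix(0, nWin * config@nChannels, length(freqs) * g)
  col <- 0L
  for (m in seq_along(freqs)) {
    for (ph in phases) {
      col <- col + 1L
      wav <- if (family == "sine") {
        makeHarmonicComplex(freqs[m], 1L, duration = config@simDuration,
                            levelDb = levelsDb[m], phases = ph, rate = rate)
      } else {
        k <- seq_len(stackHarmonics)
        makeHarmonicComplex(freqs[m], k, duration = config@simDuration,
                            levelDb = levelsDb[m], phases = ph,
                            amplitudes = 1 / k, rate = rate)
      }
      resp <- simulateAN(wav, config)
      v <- vectorizeResponse(resp)
      peak <- max(abs(v))
      if (peak == 0)
        stop("degenerate (all-zero) atom at f_d = ", freqs[m], " Hz")
      atoms[, col] <- v / peak
    }
  }
  dict <- new("Dictionary", atoms = atoms, freqs = freqs,
              nGroups = as.integer(g), phases = phases, family = family,
              levels = levelsDb, peripheryConfig = config, rate = rate)
  .dictCache[[key]] <- dict
  if (!is.null(cacheDir)) {
    dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(dict, file.path(cacheDir, paste0("dict-", key, ".rds")))
  }
  dict
}

#' Build a dictionary of pure-tone atoms
#'
#' Simulates the periphery on `M` pure tones with frequencies spaced on the
#' ERB-number scale over `freqRange`, for each of `g` starting phases
#' (`2*pi*k/g`, k = 0..g-1), and stores the vectorized, peak-normalized
#' responses as columns. Atom levels are either a single fixed dB SPL value
#' or, given a length-2 range, drawn once per atom frequency from a seeded
#' uniform distribution (all phases of a group share the level).
#'
#' @param M number of atom frequencies (>= 2).
#' @param g phases per frequency group (>= 1).
#' @param level probe level in dB SPL: a single value, or `c(min, max)` for
#'   seeded uniform sampling.
#' @param freqRange atom frequency range, Hz (within the periphery's CF
#'   bounds; components must stay below Nyquist).
#' @param config a [PeripheryConfig-class].
#' @param rate sampling rate, samples/s.
#' @param levelSeed RNG seed used when `level` is a range.
#' @param cacheDir optional directory for a content-addressed disk cache, so
#'   repeated builds with identical parameters are read back instead of
#'   resimulated.
#' @return a [Dictionary-class].
#' @export
buildSineDictionary <- function(M, g = 1, level = 30,
                                freqRange = c(125, 20000),
                                config = peripheryConfig(), rate = 1e5,
                                levelSeed = 1, cacheDir = NULL) {
  stopifnot(M >= 2, g >= 1, length(freqRange) == 2L)
  if (freqRange[2L] >= rate / 2) stop("atom frequency at or above Nyquist")
  freqs <- erbSpace(M, freqRange[1L], freqRange[2L])
  levelsDb <- if (length(level) == 2L) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(levelSeed))
    runif(M, level[1L], level[2L])
  } else rep(level, M)
  buildDictionary(freqs, as.integer(g), levelsDb, "sine", config, rate,
                  cacheDir = cacheDir)
}

#' Build a dictionary of harmonic-stack atoms
#'
#' Atoms are peripheral responses to six-harmonic complexes with linearly
#' decreasing component amplitudes (1, 1/2, ..., 1/6) at a fixed 40 dB SPL.
#' The top atom fundamental is capped at `fMax / 6` so the highest stack
#' component stays within the periphery's CF ceiling.
#'
#' @param M number of atom frequencies (>= 2).
#' @param g phases per frequency group.
#' @param level probe level, dB SPL.
#' @param freqRange fundamental range, Hz; the upper end is clamped to
#'   `config@cfMax / 6`.
#' @param config a [PeripheryConfig-class].
#' @param rate sampling rate, samples/s.
#' @param cacheDir optional disk-cache directory.
#' @return a [Dictionary-class].
#' @export
buildStackDictionary <- function(M, g = 1, level = 40,
                                 freqRange = c(125, NA),
                                 config = peripheryConfig(), rate = 1e5,
                                 cacheDir = NULL) {
  stopifnot(M >= 2, g >= 1)
  top <- config@cfMax / 6
  if (is.na(freqRange[2L]) || freqRange[2L] > top) freqRange[2L] <- top
  freqs <- erbSpace(M, freqRange[1L], freqRange[2L])
  buildDictionary(freqs, as.integer(g), rep(level, M), "stack", config,
                  rate, cacheDir = cacheDir)
}
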