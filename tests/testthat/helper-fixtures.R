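## Shared fixtures, built lazily once per test run. Dictionary builds are the
## expensive part, so the presets used by several files are memoised here.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## small dictionary for unit/property tests (fast, coarse)
tinyDict <- function() getFixture("tinyDict", function() {
  cfg <- peripheryConfig(nChannels = 48, cfMax = 6000, mode = "linear")
  buildSineDictionary(M = 72, g = 1, level = 30, freqRange = c(125, 5000),
                      config = cfg)
})

tinySieve <- function() getFixture("tinySieve", function() {
  buildSieve(sieveGrid(tinyDict()), fMax = 6000)
})

## desk preset, saturating periphery: missing-fundamental / level invariance
deskDict <- function() getFixture("deskDict", function() {
  cfg <- peripheryConfig(nChannels = 100, mode = "saturating")
  buildSineDictionary(M = 250, g = 1, level = 30, config = cfg)
})

deskSieve <- function() getFixture("deskSieve", function() {
  buildSieve(sieveGrid(deskDict()))
})

## full-resolution linear preset: resolved/unresolved and pitch shift
fullDict <- function() getFixture("fullDict", function() {
  cfg <- peripheryConfig(nChannels = 200, mode = "linear")
  buildSineDictionary(M = 1000, g = 1, level = 30, config = cfg)
})

fullSieve <- function() getFixture("fullSieve", function() {
  buildSieve(sieveGrid(fullDict()))
})

## the five-stimulus resolved/unresolved battery (shared by two criteria)
resolvedBattery <- function() getFixture("resolvedBattery", function() {
  suppressWarnings(runResolvedUnresolved(
    fullDict(), fullSieve(),
    solver = solverConfig(normalize = TRUE, maxIter = 20000)))
})

## local sieve grid step (Hz) at frequency f
gridStepAt <- function(sieve, f) {
  g <- pitchGrid(sieve)
  i <- which.min(abs(g - f))
  if (i == 1L) g[2L] - g[1L] else g[i] - g[i - 1L]
}

## pitch-estimate tolerance: one sieve grid bin or 2% of the target,
## whichever is larger
pitchTol <- function(sieve, f) max(gridStepAt(sieve, f), 0.02 * f)

## Independent coordinate-descent LASSO oracle for
## 0.5 * ||v - D h||^2 + (lambda/2) * ||h||_1 (signed coefficients).
cdLasso <- function(v, D, lambda, maxSweeps = 20000, tol = 1e-13) {
  p <- ncol(D)
  h <- numeric(p)
  r <- v
  d2 <- colSums(D^2)
  thr <- lambda / 2
  for (s in seq_len(maxSweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (d2[j] == 0) next
      rho <- sum(D[, j] * r) + d2[j] * h[j]
      hNew <- sign(rho) * max(0, abs(rho) - thr) / d2[j]
      if (hNew != h[j]) {
        r <- r - D[, j] * (hNew - h[j])
        delta <- max(delta, abs(hNew - h[j]))
        h[j] <- hNew
      }
    }
    if (delta < tol) break
  }
  obj <- 0.5 * sum((v - D %*% h)^2) + thr * sum(abs(h))
  list(h = h, objective = obj)
}

## nearest sieve-grid index for each frequency
localGridIndex <- function(sieve, freqs) {
  vapply(freqs, function(f) which.min(abs(pitchGrid(sieve) - f)), integer(1))
}

## indices of the k tallest strict local maxima of a vector
localMaximaIdx <- function(y, k) {
  n <- length(y)
  lm <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  utils::head(lm[order(y[lm], decreasing = TRUE)], k)
}

## power spectrum helper: mean squared magnitude in a band
bandPower <- function(x, rate, lo, hi) {
  sp <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * rate / length(x)
  sel <- f >= lo & f <= hi
  mean(sp[sel])
}

## write a minimal 16-bit PCM WAV (independent of the package's reader)
writeTestWav <- function(path, channels, rate) {
  stopifnot(is.matrix(channels))
  inter <- as.integer(round(pmax(-1, pmin(1, t(channels))) * 32767))
  dataSize <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  nCh <- ncol(channels)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(nCh, con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * nCh * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(nCh * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}

## write a minimal 16-bit PCM AIFF (mono), 44100 Hz fixed
writeTestAiff <- function(path, x) {
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  dataSize <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FORM", con, eos = NULL)
  writeBin(as.integer(4L + 26L + 16L + dataSize), con, size = 4,
           endian = "big")
  writeChar("AIFF", con, eos = NULL)
  writeChar("COMM", con, eos = NULL)
  writeBin(18L, con, size = 4, endian = "big")
  writeBin(1L, con, size = 2, endian = "big")              # channels
  writeBin(length(pcm), con, size = 4, endian = "big")     # frames
  writeBin(16L, con, size = 2, endian = "big")             # bits
  # 44100 Hz as IEEE 80-bit extended
  writeBin(as.raw(c(0x40, 0x0E, 0xAC, 0x44, 0, 0, 0, 0, 0, 0)), con)
  writeChar("SSND", con, eos = NULL)
  writeBin(as.integer(8L + dataSize), con, size = 4, endian = "big")
  writeBin(0L, con, size = 4, endian = "big")              # offset
  writeBin(0L, con, size = 4, endian = "big")              # block size
  writeBin(pcm, con, size = 2, endian = "big")
  invisible(path)
}
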